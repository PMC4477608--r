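test_that("the association statistic is n r^2 with chi-squared(1) calibration", {
  # perfect correlation: chi2 = n
  n <- 100
  trait <- rnorm(n)
  geno <- matrix(scale(trait), ncol = 1, dimnames = list(NULL, "s1"))
  expect_equal(assoc_chi2(geno, trait)$chi2, n)

  # independent dosages: mean chi2 ~ 1 (chi-squared 1 df), p ~ uniform
  set.seed(3)
  geno0 <- matrix(rbinom(200 * 2000, 2, 0.4), nrow = 200)
  trait0 <- rnorm(200)
  r <- assoc_chi2(geno0, trait0)
  expect_lt(abs(mean(r$chi2) - 1), 0.1)
  expect_lt(abs(mean(r$p_raw < 0.05) - 0.05), 0.02)

  # monomorphic SNP -> NA, not zero
  mono <- matrix(c(rep(1, 10), 0:9 %% 3), ncol = 2)
  expect_true(is.na(assoc_chi2(mono, rnorm(10))$chi2[1]))
  expect_false(is.na(assoc_chi2(mono, rnorm(10))$chi2[2]))
})

test_that("missing dosages are handled pairwise-complete", {
  g <- c(0, 1, 2, NA, 2, 0)
  t <- c(0.1, 1, 2.2, 5, 1.8, 0)
  geno <- matrix(g, ncol = 1)
  ok <- !is.na(g)
  expect_equal(assoc_chi2(geno, t)$chi2,
               sum(ok) * cor(g[ok], t[ok])^2)
})

# all 6 permutations of 3 elements, one per row
combinat_perms3 <- function() {
  rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
        c(3, 1, 2), c(3, 2, 1))
}

make_breed_data <- function(n_breeds = 8, per_breed = 10, n_snps = 50,
                            seed = 1) {
  set.seed(seed)
  breed <- rep(paste0("b", seq_len(n_breeds)), each = per_breed)
  p <- matrix(runif(n_breeds * n_snps, 0.1, 0.9), nrow = n_breeds)
  geno <- matrix(rbinom(length(breed) * n_snps, 2,
                        p[rep(seq_len(n_breeds), each = per_breed), ]),
                 nrow = length(breed))
  colnames(geno) <- paste0("s", seq_len(n_snps))
  list(breed = breed, geno = geno,
       samples = data.frame(sample = paste0("i", seq_along(breed)),
                            breed = breed))
}

test_that("breed permutation p-values respect their floor and ordering", {
  d <- make_breed_data(seed = 2)
  # plant one SNP perfectly aligned with breed trait
  trait_breed <- rnorm(8)
  trait <- data.frame(sample = d$samples$sample, breed = d$breed,
                      value = trait_breed[as.integer(factor(d$breed))])
  d$geno[, 1] <- round(2 * (rank(trait$value) / length(trait$value)))
  r <- breed_permutation_test(d$geno, trait, n_perm = 99, seed = 5)
  expect_true(all(r$emp1 >= 1 / 100 & r$emp1 <= 1, na.rm = TRUE))
  expect_true(all(r$emp2 >= r$emp1, na.rm = TRUE))
})

test_that("a permutation-invariant (constant) trait gives EMP2 = 1 everywhere", {
  d <- make_breed_data(seed = 3)
  trait <- data.frame(sample = d$samples$sample, breed = d$breed, value = 5)
  r <- breed_permutation_test(d$geno, trait, n_perm = 50, seed = 1)
  expect_true(all(r$emp1 == 1))
  expect_true(all(r$emp2 == 1))
})

test_that("EMP1 converges to the exact value enumerated over all relabelings", {
  # 3 breeds -> 6 equally likely breed relabelings; enumerate the tie
  # probability of the statistic exactly and compare to the sampled EMP1
  set.seed(9)
  per <- 25
  breed <- rep(c("a", "b", "c"), each = per)
  geno <- matrix(c(rbinom(per, 2, 0.1), rbinom(per, 2, 0.5),
                   rbinom(per, 2, 0.95)), ncol = 1)
  vals <- c(a = 1, b = 2, c = 10)
  trait <- data.frame(sample = seq_along(breed), breed = breed,
                      value = unname(vals[breed]))
  stat_of <- function(v) {
    tv <- v[match(breed, c("a", "b", "c"))]
    length(tv) * cor(geno[, 1], tv)^2
  }
  obs <- stat_of(vals)
  perms <- combinat_perms3()
  stats <- apply(perms, 1, function(ix) stat_of(vals[ix]))
  p_ge <- mean(stats >= obs - 1e-12)     # exact tie probability
  P <- 1200
  r <- breed_permutation_test(geno, trait, n_perm = P, seed = 7)
  se <- sqrt(p_ge * (1 - p_ge) / P)
  expect_lt(abs(r$emp1 - (1 + P * p_ge) / (P + 1)), 4 * se + 1e-3)
  expect_error(breed_permutation_test(
    geno, data.frame(sample = 1:3, breed = "a", value = 1)), "2 breeds")
})

test_that("sample order does not change permutation results", {
  d <- make_breed_data(seed = 4, n_snps = 20)
  trait_breed <- rnorm(8)
  trait <- data.frame(sample = d$samples$sample, breed = d$breed,
                      value = trait_breed[as.integer(factor(d$breed))])
  r1 <- breed_permutation_test(d$geno, trait, n_perm = 60, seed = 11)
  ord <- sample(nrow(d$geno))
  r2 <- breed_permutation_test(d$geno[ord, ], trait[ord, ],
                               n_perm = 60, seed = 11)
  expect_equal(r1$emp1, r2$emp1)
  expect_equal(r1$emp2, r2$emp2)
})

test_that("Kruskal-Wallis reproduces hand-computed rank arithmetic", {
  # groups {1,2,3} vs {4,5,6}: H = 12/(6*7) * (3*(2-3.5)^2 + 3*(5-3.5)^2)
  panel <- data.frame(ear_type = rep(c("drop", "prick"), each = 3),
                      body_mass_kg = 1:6)
  kw <- kruskal_wallis_mass_by_ear(panel)
  expect_equal(kw$H, 3.857, tolerance = 5e-4)
  # all masses equal -> H = 0 under tie correction (NaN avoided by R's test?)
  panel2 <- data.frame(ear_type = rep(c("drop", "prick"), each = 3),
                       body_mass_kg = 7)
  expect_true(is.nan(kruskal_wallis_mass_by_ear(panel2)$H) ||
                kruskal_wallis_mass_by_ear(panel2)$H == 0)
  expect_error(kruskal_wallis_mass_by_ear(
    data.frame(ear_type = "drop", body_mass_kg = 1)), "2 ear classes")
})

test_that("among-breed FST matches closed forms", {
  mk <- function(p_by_breed, per = 50) {
    breed <- rep(paste0("b", seq_along(p_by_breed)), each = per)
    dos <- unlist(lapply(p_by_breed, function(p) {
      k <- round(2 * per * p)   # exact allele counts
      c(rep(2, k %/% 2), rep(1, k %% 2), rep(0, per - k %/% 2 - k %% 2))
    }))
    list(geno = matrix(dos, ncol = 1, dimnames = list(NULL, "s")),
         breed = breed)
  }
  # opposite fixation -> FST = 1
  x <- mk(c(1, 0))
  expect_equal(amongbreed_fst_scan(x$geno, x$breed)$snps$fst, 1)
  # identical frequencies -> FST = 0
  y <- mk(c(0.5, 0.5))
  expect_equal(amongbreed_fst_scan(y$geno, y$breed)$snps$fst, 0)
  # p = {1, 0, 0.5, 0.5}: H_T = 0.5, H_S = 0.25 -> FST = 0.5
  z <- mk(c(1, 0, 0.5, 0.5))
  expect_equal(amongbreed_fst_scan(z$geno, z$breed)$snps$fst, 0.5)
})

test_that("qualifying SNPs form ranked maximal runs", {
  set.seed(5)
  n_b <- 6; per <- 20; n_s <- 30
  breed <- rep(paste0("b", 1:n_b), each = per)
  # differentiated SNPs at positions 5:9 and 20:21 (runs of 5 and 2)
  p <- matrix(0.5, nrow = n_b, ncol = n_s)
  p[, c(5:9, 20:21)] <- rep(c(0.02, 0.98), length.out = n_b)
  geno <- matrix(rbinom(n_b * per * n_s, 2,
                        p[rep(1:n_b, each = per), ]), nrow = n_b * per)
  colnames(geno) <- paste0("s", 1:n_s)
  map <- data.frame(snp = colnames(geno), chrom = "chr10",
                    pos = (1:n_s) * 1000)
  scan <- amongbreed_fst_scan(geno, breed, map = map)
  runs <- scan$runs
  expect_equal(runs$n_snps[1], 5)
  expect_equal(runs$start[1], 5000)
  expect_equal(runs$end[1], 9000)
  expect_true(2 %in% runs$n_snps)
})

test_that("trait vectors broadcast breed values and reject unknown breeds", {
  panel <- data.frame(breed = c("x", "y"), ear_code = c(1, 3),
                      body_mass_kg = c(10, 30))
  smp <- data.frame(sample = c("s1", "s2", "s3"), breed = c("x", "y", "x"))
  tv <- trait_vector(smp, panel, "ear")
  expect_equal(tv$value, c(1, 3, 1))
  expect_equal(trait_vector(smp, panel, "mass")$value, c(10, 30, 10))
  expect_error(trait_vector(data.frame(sample = "s", breed = "z"),
                            panel, "ear"), "absent")
})
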