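# Independent likelihood oracle for 2-SNP phasing instances: grid search
# over the 3-simplex of the 4 haplotype frequencies, refined by Nelder-Mead
# on softmax parameters. Built from first principles (explicit genotype
# probabilities), sharing no code with em_phase().
oracle_loglik <- function(f, geno) {
  # f named by haplotypes "00","01","10","11"; geno n x 2 dosage matrix
  haps <- c("00", "01", "10", "11")
  a1 <- c(0, 0, 1, 1); a2 <- c(0, 1, 0, 1)
  ll <- 0
  for (s in seq_len(nrow(geno))) {
    pr <- 0
    for (i in 1:4) for (j in 1:4) {
      if (a1[i] + a1[j] == geno[s, 1] && a2[i] + a2[j] == geno[s, 2]) {
        pr <- pr + f[i] * f[j]
      }
    }
    ll <- ll + log(pr)
  }
  ll
}

oracle_mle <- function(geno, step = 0.02) {
  grid <- expand.grid(a = seq(0, 1, step), b = seq(0, 1, step),
                      c = seq(0, 1, step))
  grid <- grid[grid$a + grid$b + grid$c <= 1 + 1e-12, ]
  best <- -Inf; best_f <- NULL
  for (k in seq_len(nrow(grid))) {
    f <- c(grid$a[k], grid$b[k], grid$c[k],
           max(0, 1 - grid$a[k] - grid$b[k] - grid$c[k]))
    f <- pmax(f, 1e-12); f <- f / sum(f)
    ll <- oracle_loglik(f, geno)
    if (ll > best) { best <- ll; best_f <- f }
  }
  # refine with Nelder-Mead on softmax parameters
  obj <- function(theta) {
    f <- exp(theta) / sum(exp(theta))
    -oracle_loglik(pmax(f, 1e-12), geno)
  }
  opt <- stats::optim(log(pmax(best_f, 1e-6)), obj,
                      control = list(maxit = 2000, reltol = 1e-12))
  f <- exp(opt$par) / sum(exp(opt$par))
  names(f) <- c("00", "01", "10", "11")
  f
}

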