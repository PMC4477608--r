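pool	breeds	n	size_class	ear_class	kind	mean_depth	is_wolf
BT	Border Terrier	5	small	non-drop	SC	4748	FALSE
JR	Jack Russell Terrier	5	small	non-drop	SC	4910	FALSE
GS	German Shepherd	5	large	non-drop	SC	5182	FALSE
WEI	Weimaraner	5	large	drop	SC	4305	FALSE
ESS	English Springer Spaniel	5	large	drop	SC	1990	FALSE
Pool1	Wolf	12	large	non-drop	WGS	7.5	TRUE
Pool2	Smaland Hound;Norwegian Elkhound;Swedish Elkhound;Finnish Lapphund	12	large	mixed	WGS	6.9	FALSE
Pool3	Cocker Spaniel;Springer Spaniel;Golden Retriever;Labrador Retriever	12	large	drop	WGS	6.1	FALSE
Pool4	Drever	12	large	drop	WGS	8.0	FALSE
Pool5	Belgian Tervuren	12	large	non-drop	WGS	8.1	FALSE
Pool6	Bearded Collie;Hovawart;Riesenschnauzer;German Shepherd	12	large	mixed	WGS	7.9	FALSE
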