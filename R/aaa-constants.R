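# Species and rate-constant vocabulary shared across the package.
# The seven dynamic phosphoforms are the two kinase phosphoforms (CheA2-P,
# CheA3-P) and the five response-regulator phosphoforms; unphosphorylated
# partners are always derived from conservation (X = XT - XP), never stored.

.species <- c("A2P", "A3P", "Y3P", "Y4P", "Y6P", "B1P", "B2P")
.rr_species <- c("Y3P", "Y4P", "Y6P", "B1P", "B2P")
.totals <- c("A2T", "A3T", "Y3T", "Y4T", "Y6T", "B1T", "B2T")
.proteins <- c(CheA2 = "A2T", CheA3 = "A3T", CheY3 = "Y3T", CheY4 = "Y4T",
               CheY6 = "Y6T", CheB1 = "B1T", CheB2 = "B2T")
.first_order_rates <- c("k1", "k2", "k10", "k11", "k12", "k13", "k14")
.second_order_rates <- c("k3", "k3r", "k4", "k4r", "k5", "k5r", "k6", "k6r",
                         "k7", "k7r", "k8", "k8r", "k9", "k9r", "k15a", "k15b")
.rate_names <- c(.first_order_rates, .second_order_rates)

# totals paired with each phosphoform
.total_of <- c(A2P = "A2T", A3P = "A3T", Y3P = "Y3T", Y4P = "Y4T",
               Y6P = "Y6T", B1P = "B1T", B2P = "B2T")
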