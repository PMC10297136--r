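# Small hand-checkable fixtures shared across test files.

# 4 patients x 4 genes; gene supports: g1 {1,2}, g2 {1,3}, g3 {2,4}, g4 {4}
toy_matrix <- function() {
  mutation_matrix(rbind(c(1, 1, 0, 0),
                        c(1, 0, 1, 0),
                        c(0, 1, 0, 0),
                        c(0, 0, 1, 1)),
                  patient_ids = paste0("P", 1:4),
                  gene_ids = c("TP53", "KRAS", "EGFR", "STK11"))
}

# matrix realizing the worked scoring example: two genes with supports
# {1,2,3} and {3,4} on 5 patients
overlap_matrix <- function() {
  mutation_matrix(cbind(gA = c(1, 1, 1, 0, 0),
                        gB = c(0, 0, 1, 1, 0)))
}

# disjoint supports of sizes 3 and 4 on 10 patients
disjoint_matrix <- function() {
  E <- matrix(0L, 10, 2)
  E[1:3, 1] <- 1L
  E[4:7, 2] <- 1L
  mutation_matrix(E)
}

random_standardized <- function(n) {
  x <- stats::rnorm(n)
  (x - mean(x)) / sqrt(mean((x - mean(x))^2))
}
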