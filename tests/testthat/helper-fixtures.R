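# Shared helpers for building in-code fixtures.

# Map generator truth labels to classifier categories for a high_parent=P1
# trio.
truth_to_category <- c(
  equal_high = "equal_P1", equal_low = "equal_P2",
  over_parents = "over_parents", between_parents = "between_parents",
  null_equal = "non_deg"
)

# Random symmetric diallel cell-mean table.
random_diallel_table <- function(p, with_diagonal = TRUE) {
  m <- matrix(rnorm(p * p, 50, 10), p)
  m <- (m + t(m)) / 2
  if (!with_diagonal) diag(m) <- NA_real_
  diallel_means(m)
}

# Small count matrix with named genes/samples.
make_counts <- function(x, samples = c("A", "B")) {
  m <- matrix(as.integer(x), ncol = length(samples))
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))), samples)
  m
}

# Brute-force independent re-derivation of the trio category from
# significance flags and the F1's position relative to the parental range.
# Used as the truth-table oracle for classify_trio().
oracle_trio_category <- function(deg1, deg2, sig1, sig2, position) {
  if (!deg1 && !deg2) return("non_deg")
  s1 <- sig1; s2 <- sig2
  if (!s1 && !s2) { s1 <- deg1; s2 <- deg2 }
  if (s1 && s2) {
    if (position == "outside") "over_parents" else "between_parents"
  } else if (s1) "equal_P2" else "equal_P1"
}
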