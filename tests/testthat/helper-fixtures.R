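# small fixtures built in code

toy_counts <- function() {
  tibble::tibble(
    sample_id = c("a", "b", "c"),
    Bacteroides = c(4, 1, 0),
    Lactobacillus = c(4, 1, 6),
    Prevotella = c(2, 2, 4)
  )
}

# distance matrix of two tight, well-separated 4-point groups
two_group_dist <- function(within = 0.05, between = 0.5) {
  pos <- c(0, within, 2 * within, 3 * within,
           between, between + within, between + 2 * within, between + 3 * within)
  d <- as.matrix(dist(pos))
  dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  d
}

random_probability_matrix <- function(n, t) {
  p <- matrix(rgamma(n * t, shape = 1), n)
  p <- p / rowSums(p)
  colnames(p) <- paste0("T", seq_len(t))
  rownames(p) <- paste0("S", seq_len(n))
  p
}

# brute-force k-medoids optimum by exhaustive enumeration
brute_force_pam_cost <- function(d, k) {
  combos <- utils::combn(nrow(d), k)
  min(apply(combos, 2, function(med) {
    sum(apply(d[, med, drop = FALSE], 1, min))
  }))
}

producer_candidates <- c(
  "Faecalibacterium", "Butyricicoccus", "Eubacterium hallii group",
  "Butyricimonas", "Blautia", "Anaerostipes", "Coprococcus",
  "Oscillospira", "Roseburia"
)
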