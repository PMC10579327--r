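# Independent oracles used against the package implementation.

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# C(N, n) draws: items 1..K are the "successes".
enum_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Benjamini-Hochberg by the definition: adj_(i) = min_{j >= i} p_(j) * m / j.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Set-semantics oracle for unordered edge deduplication.
dedup_pairs_oracle <- function(a, b) {
  keep <- a != b
  key <- paste(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]), sep = "|")
  sort(unique(key))
}

# Tiny three-source catalog fixture used in several files.
tiny_sources <- function() {
  list(
    ge = tibble::tibble(
      symbol = c("VHL", "CRBN", "AAA1", "BBB2"),
      lit_validated = c(TRUE, TRUE, FALSE, TRUE)),
    ubihub = tibble::tibble(
      symbol = c("VHL", "CRBN", "CCC3"),
      function_text = c("RING E3 ligase", "E3 ubiquitin ligase",
                        "ubiquitin conjugating enzyme")),
    ubibrowser = tibble::tibble(
      symbol = c("VHL", "CRBN", "AAA1"),
      esi_count = c(20L, 12L, 5L))
  )
}

# Small bundle shared by generator/search unit tests (built once per run).
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "e3select-small-bundle")
      cfg <- sim_config(seed = 42, n_ligases = 40, n_targets = 200,
                        n_tumor_types = 4, n_normal_tissues = 5,
                        samples_per_tissue = 8, cells_per_tissue = 60,
                        n_co_opted = 5, n_clinical = 2, n_case1_passers = 3)
      manifest <- generate_bundle(cfg, dir)
      atlas <- suppressMessages(build_atlas(dir))
      cache <<- list(dir = dir, config = cfg, manifest = manifest,
                     atlas = atlas)
    }
    cache
  }
})
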