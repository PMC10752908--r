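# Shared fixtures, built in code and cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small curated planted-motif dataset (no injected noise rows).
tiny_curated <- function(n_act = 40, n_ina = 40, label_noise = 0, seed = 11) {
  key <- paste("cur", n_act, n_ina, label_noise, seed, sep = "_")
  cached(key, {
    raw <- gen_labeled_smiles(synthetic_spec(
      n_active = n_act, n_inactive = n_ina, label_noise = label_noise,
      seed = seed))
    dplyr::left_join(curate_compounds(raw),
                     raw[, c("id", "true_class", "motif")], by = "id")
  })
}

# A separable FP4 block: a handful of columns equal the class indicator.
separable_block <- function(data, seed = 5) {
  gen_fp_block(data, "FP4", signal_frac = 0.02, flip_prob = 0,
               seed = seed)
}

# Random confusion counts for metric property checks.
random_counts <- function(seed) {
  withr::with_seed(seed, {
    list(TP = sample(0:20, 1), TN = sample(0:20, 1),
         FP = sample(0:20, 1), FN = sample(0:20, 1))
  })
}

# Brute-force AUC: exhaustive pair counting, ties worth 1/2.
auc_brute <- function(scores, y01) {
  pos <- scores[y01 == 1]; neg <- scores[y01 == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Closed-form MCC, written out independently of the package internals.
mcc_closed_form <- function(tp, tn, fp, fn) {
  d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (d == 0) return(0)
  (tp * tn - fp * fn) / sqrt(d)
}
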