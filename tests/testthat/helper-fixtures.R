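# Shared fixtures. Expensive objects (trained autoencoders) are memoized so
# several test files can reuse one training run within a session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small noiseless spectrum on the standard grid: two Gaussian bands plus a
# linear baseline, handy for preprocessing oracles.
toy_spectrum <- function(slope = 1e-5, offset = 0.1) {
  wn <- seq(4000, 1000, by = -2)
  a <- 0.8 * exp(-0.5 * ((wn - 1650) / 25)^2) +
    0.4 * exp(-0.5 * ((wn - 2900) / 15)^2) +
    offset + slope * (wn - 1000)
  list(wavenumber = wn, absorbance = a)
}

# Small but realistic cohort (defaults, n patients per class).
small_cohort <- function(n = 6, seed = 101, ...) {
  generate_cohort(synth_config(n_patients_per_class = n, seed = seed, ...))
}

# Quick training configuration for unit tests that only need a fitted model,
# not a good one.
quick_ae_config <- function(max_epochs = 60, ...) {
  ae_train_config(max_epochs = max_epochs, patience = max_epochs,
                  validation_fraction = 0, ...)
}

# A quickly fitted autoencoder on a tiny cohort; shared across test files.
quick_fitted_ae <- function() {
  cached("quick_ae", {
    pp <- preprocess_set(small_cohort(n = 4, seed = 303))
    list(model = autoencoder(pp, config = quick_ae_config(), seed = 5),
         processed = pp)
  })
}

# Fully trained autoencoder on the default cohort (n = 20/class, defaults).
# Shared by the sensitivity invariants and the acceptance checks; trains
# once per session (about two minutes).
default_trained_ae <- function() {
  cached("default_ae", {
    pp <- preprocess_set(generate_cohort(
      synth_config(n_patients_per_class = 20, seed = 11)))
    list(model = autoencoder(pp, seed = 7), processed = pp)
  })
}

# Latent-level two-group fixture with a prescribed standardized mean
# difference on feature 1 and pure noise elsewhere. delta = qnorm(bayes_auc)
# * sqrt(2) gives a single-feature Bayes AUC of bayes_auc.
latent_group_fixture <- function(n_pos = 9, n_neg = 16, k = 4,
                                 bayes_auc = 0.95, seed = 1) {
  delta <- stats::qnorm(bayes_auc) * sqrt(2)
  set.seed(seed)
  x <- matrix(stats::rnorm((n_pos + n_neg) * k), n_pos + n_neg, k)
  colnames(x) <- paste0("F", seq_len(k))
  y <- factor(rep(c("cirrhosis", "HCC"), c(n_neg, n_pos)),
              levels = c("cirrhosis", "HCC"))
  x[y == "HCC", 1] <- x[y == "HCC", 1] + delta
  list(x = x, y = y, delta = delta)
}
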