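# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# 10-casualty cohort generated through the full funnel under a fixed seed.
mini_cohort <- function() {
  fixture("mini_cohort", function() make_mini_cohort(3, n_f = 10))
}

# A small trained forecaster on the mini cohort (folds 1-3 train, 4 val),
# enough to exercise prediction plumbing; accuracy is not the point here.
tiny_predictor <- function() {
  fixture("tiny_predictor", function() {
    coh <- mini_cohort()
    ids <- vapply(coh$casualties, `[[`, numeric(1), "id")
    train_fold(trajectory_samples(coh, ids[coh$fold %in% 1:3]),
               trajectory_samples(coh, ids[coh$fold == 4]),
               gru_config(hidden = 8, epochs = 6, batch_size = 8,
                          patience = 6),
               seed = 5)
  })
}

# Random toy forecasting sample of given horizon for metric tests.
toy_sample <- function(Tw = 3, Tr = 4) {
  list(warm = cbind(u = stats::runif(Tw, 0, 1.1),
                    hr = stats::runif(Tw, 70, 150),
                    sbp = stats::runif(Tw, 80, 120)),
       init = c(stats::runif(1, 70, 150), stats::runif(1, 80, 120)),
       u = stats::runif(Tr, 0, 1.1),
       tgt = cbind(hr = stats::runif(Tr, 70, 150),
                   sbp = stats::runif(Tr, 80, 120)))
}
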