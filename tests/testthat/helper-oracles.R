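# Independent brute-force oracle for the pooled-covariance Gaussian
# discriminant: plain loops and solve(), no shared code with the package's
# fitting path.
brute_force_lda_predict <- function(train, test,
                                    feats = c("DFB1", "DFA2", "PF", "FR",
                                              "duration")) {
  classes <- sort(unique(train$caller_id))
  Xtr <- as.matrix(train[, feats])
  n <- nrow(Xtr); k <- length(classes); p <- ncol(Xtr)
  means <- list(); priors <- numeric(k)
  S <- matrix(0, p, p)
  for (i in seq_len(k)) {
    Xi <- Xtr[train$caller_id == classes[i], , drop = FALSE]
    means[[i]] <- colMeans(Xi)
    priors[i] <- nrow(Xi) / n
    Xc <- sweep(Xi, 2, means[[i]])
    S <- S + t(Xc) %*% Xc
  }
  W <- S / (n - k)
  Winv <- solve(W)
  Xte <- as.matrix(test[, feats])
  pred <- character(nrow(Xte))
  for (r in seq_len(nrow(Xte))) {
    sc <- vapply(seq_len(k), function(i) {
      m <- means[[i]]
      as.numeric(Xte[r, ] %*% Winv %*% m - 0.5 * t(m) %*% Winv %*% m +
                   log(priors[i]))
    }, numeric(1))
    pred[r] <- classes[which.max(sc)]
  }
  pred
}

# Pure sine waveform helper.
tone <- function(freq, dur_s = 0.3, rate = 44100, amp = 0.8) {
  waveform(amp * sin(2 * pi * freq * (seq_len(round(dur_s * rate)) - 1) / rate),
           rate)
}

# A small labelled feature table with random Gaussian classes.
random_feature_table <- function(n_callers = 3, units_per_caller = 10,
                                 sep = 1, seed = 1) {
  spec <- call_sim_spec(n_callers = n_callers, bouts_per_caller = 2,
                        units_per_bout = c(ceiling(units_per_caller / 2),
                                           ceiling(units_per_caller / 2)),
                        between_caller_sd = sep, within_caller_sd = 1,
                        bout_sd = 0, seed = seed)
  gen_call_features(spec)
}

# Small troop for the dyad-selection toys: explicit affinity matrix.
toy_troop_matrices <- function() {
  ids <- c("S", "F1", "F2", "F3", "F4", "M1")
  sexes <- stats::setNames(c("F", "F", "F", "F", "F", "M"), ids)
  a <- matrix(0, 6, 6, dimnames = list(ids, ids))
  a["S", "F1"] <- a["F1", "S"] <- 10   # subject's top friend
  a["S", "F2"] <- a["F2", "S"] <- 1
  a["S", "F3"] <- a["F3", "S"] <- 0
  a["S", "F4"] <- a["F4", "S"] <- 5
  a["F1", "F2"] <- a["F2", "F1"] <- 8  # F2: friend of F1, low with S
  a["F1", "F3"] <- a["F3", "F1"] <- 1
  a["F2", "F3"] <- a["F3", "F2"] <- 2
  a["F4", "M1"] <- a["M1", "F4"] <- 3
  list(ids = ids, sexes = sexes, assoc = a)
}
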