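# Independent reference implementations used as oracles. These are written
# from the definitions, deliberately naive, and share no code with the
# package internals.

# exhaustive double-loop pair matrix: strict >, ties 0, lexicographic
# canonical orientation
naive_pair_matrix <- function(vals) {
  ids <- sort(rownames(vals))
  g <- length(ids)
  pairs <- list()
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      a <- ids[i]
      b <- ids[j]
      row <- numeric(ncol(vals))
      for (s in seq_len(ncol(vals))) {
        row[s] <- if (vals[a, s] > vals[b, s]) 1 else 0
      }
      pairs[[paste(a, b, sep = "|")]] <- row
    }
  }
  out <- do.call(rbind, pairs)
  colnames(out) <- colnames(vals)
  out
}

# naive Efron/Breslow log partial likelihood by explicit loops over event
# times
naive_cox_loglik <- function(time, event, x, beta, ties = "efron") {
  x <- as.matrix(x)
  eta <- as.numeric(x %*% beta)
  ll <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    dset <- which(time == t0 & event == 1)
    rset <- which(time >= t0)
    d <- length(dset)
    ll <- ll + sum(eta[dset])
    sum_r <- sum(exp(eta[rset]))
    sum_d <- sum(exp(eta[dset]))
    for (l in seq_len(d) - 1) {
      frac <- if (ties == "efron") l / d else 0
      ll <- ll - log(sum_r - frac * sum_d)
    }
  }
  ll
}

# iterated grid-search maximizer of the naive partial likelihood
grid_max_cox <- function(time, event, x, ties = "efron") {
  x <- as.matrix(x)
  p <- ncol(x)
  center <- rep(0, p)
  half <- 4
  for (round in 1:6) {
    grids <- lapply(seq_len(p), function(j) {
      seq(center[j] - half, center[j] + half, length.out = 21)
    })
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1, function(b) naive_cox_loglik(time, event, x, b, ties))
    center <- as.numeric(pts[which.max(vals), ])
    half <- half * 2 / 20 * 1.5   # next window spans three old grid steps
  }
  center
}

# Mann-Whitney probability estimate with ties counted one half
mann_whitney_auc <- function(case, ctrl) {
  s <- 0
  for (a in case) {
    for (b in ctrl) {
      s <- s + (a > b) + 0.5 * (a == b)
    }
  }
  s / (length(case) * length(ctrl))
}

# quick uncorrelated survival draw
rand_surv <- function(n, event_p = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(time = stats::rexp(n, rate = 1e-3) + 1,
       event = stats::rbinom(n, 1, event_p))
}

# the end-to-end parameter-recovery configuration: two planted pairs
# (beta = +1 / -1, four genes) plus 60 noise lncRNAs, n = 400 tumors
recovery_config <- function(seed) {
  sim_config(n_tumor = 400, n_normal = 60, n_lnc = 64, n_immune = 64,
             n_coexpressed = 64, n_de = 64, seed = seed)
}
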