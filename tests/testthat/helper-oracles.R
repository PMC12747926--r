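# Independent oracles: brute-force / enumeration implementations kept
# deliberately naive and separate from the package's code paths.

# day-by-day coverage oracle for episode merging: mark covered days, close a
# run when more than `grace` uncovered days elapse before the next fill
oracle_episodes <- function(fills, grace) {
  fills <- fills[order(fills$fill_date), , drop = FALSE]
  covered <- sort(unique(unlist(lapply(seq_len(nrow(fills)), function(i) {
    d0 <- as.integer(fills$fill_date[i])
    seq(d0, d0 + fills$days_supply[i] - 1)
  }))))
  breaks <- which(diff(covered) - 1 > grace)
  run_id <- cumsum(c(1, seq_along(covered)[-1] %in% (breaks + 1)))
  runs <- split(covered, run_id)
  out <- lapply(runs, function(r) {
    data.frame(start = as.Date(min(r), origin = "1970-01-01"),
               end = as.Date(max(r) + 1, origin = "1970-01-01"),
               covered_days = length(r))
  })
  out <- do.call(rbind, out)
  out$n_fills <- vapply(seq_len(nrow(out)), function(j) {
    sum(fills$fill_date >= out$start[j] & fills$fill_date < out$end[j])
  }, integer(1))
  rownames(out) <- NULL
  out
}

# brute-force qualification oracle: scan a 365-day window anchored at every
# outpatient date; earliest of (first inpatient, third code in best window)
oracle_qualify <- function(dx) {
  inpt <- dx$date[dx$setting == "inpatient"]
  cands <- if (length(inpt)) min(inpt) else as.Date(NA)
  outs <- sort(unique(dx$date[dx$setting == "outpatient"]))
  for (s in seq_along(outs)) {
    inside <- outs[outs >= outs[s] & outs < outs[s] + 365]
    if (length(inside) >= 3) cands <- c(cands, inside[3])
  }
  cands <- cands[!is.na(cands)]
  if (!length(cands)) as.Date(NA) else min(cands)
}

# reference interpreter for the course state machine, built on the day-by-day
# episode oracle rather than the package's merge
oracle_classify <- function(fills, index_drug, index_start, followup_end,
                            grace = 60) {
  own <- fills[fills$drug_name == index_drug, , drop = FALSE]
  eps <- oracle_episodes(own, grace)
  idx <- which(eps$start <= index_start & eps$end > index_start)
  idx_end <- eps$end[idx]
  others <- fills[fills$drug_name != index_drug & fills$fill_date >= index_start, ,
                  drop = FALSE]
  first_other <- if (nrow(others)) min(others$fill_date) else as.Date(NA)
  after_gap <- fills[fills$fill_date > idx_end + grace, , drop = FALSE]
  if (!is.na(first_other) && first_other <= idx_end + grace) {
    return(list(pattern = "switching", index_episode_end = idx_end))
  }
  if (nrow(after_gap)) {
    first <- after_gap[order(after_gap$fill_date), ][1, ]
    return(list(pattern = "restart", index_episode_end = idx_end,
                same = first$drug_name == index_drug))
  }
  if (idx_end + grace < followup_end) {
    return(list(pattern = "discontinuation", index_episode_end = idx_end))
  }
  list(pattern = "continuation", index_episode_end = idx_end)
}

# full hypergeometric enumeration for the two-sided Fisher p-value
oracle_fisher <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  amin <- max(0, c1 - (n - r1)); amax <- min(r1, c1)
  probs <- stats::dhyper(amin:amax, c1, n - c1, r1)
  pobs <- stats::dhyper(a, c1, n - c1, r1)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# closed-form Pearson statistic
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# random fill set for one person and drug
rand_fills <- function(n_fills, origin = as.Date("2014-01-01"),
                       max_gap = 120, max_supply = 45) {
  dates <- origin + cumsum(sample.int(max_gap, n_fills, replace = TRUE)) - 1
  tibble::tibble(
    person_id = "R1",
    fill_date = dates,
    days_supply = sample.int(max_supply, n_fills, replace = TRUE),
    drug_name = "naproxen",
    visit_id = NA_character_
  )
}

# classify an adversarial timeline through the package's real code path
classify_timeline <- function(tl, config = claims_config()) {
  eps <- build_episodes(tl$fills, grace = config$grace_biologic, by = "drug_name")
  classify_course(eps, tl$index_drug, tl$index_start, tl$followup_end,
                  config = config)
}
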