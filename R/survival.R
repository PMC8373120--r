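#' Kaplan--Meier product-limit estimate
#'
#' Fits the product-limit estimator (via [survival::survfit()]) on
#' right-censored records. The survival curve steps down only at event times.
#'
#' @param records Tibble with columns `time` (> 0) and `event`
#'   (1 = event, 0 = censored).
#' @return An object of class `km_fit`; use [tidy()] for the step table,
#'   [glance()] for the one-row summary, and [km_survival_at()] to evaluate
#'   the step function.
#' @export
km_estimate <- function(records) {
  assert_cols(records, c("time", "event"))
  if (nrow(records) == 0) stop_sp("km_estimate() needs at least one record")
  if (any(records$time <= 0)) stop_sp("survival times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(records))
  tab <- tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
  structure(list(fit = fit, table = tab, n = nrow(records),
                 n_events = sum(records$event)),
            class = "km_fit")
}

#' @export
tidy.km_fit <- function(x, ...) x$table

#' @export
glance.km_fit <- function(x, ...) {
  med <- unname(summary(x$fit)$table["median"])
  tibble(n = x$n, n_events = x$n_events, median_survival = med)
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier fit:", x$n, "subjects,", x$n_events, "events\n")
  print(x$table, ...)
  invisible(x)
}

#' Evaluate a Kaplan--Meier curve at given times
#'
#' @param km A `km_fit` object.
#' @param times Numeric vector of times.
#' @return Survival probabilities (right-continuous step function; 1 before
#'   the first event).
#' @export
km_survival_at <- function(km, times) {
  tab <- km$table[km$table$n_event > 0, , drop = FALSE]
  if (nrow(tab) == 0) return(rep(1, length(times)))
  sf <- stats::stepfun(tab$time, c(1, tab$survival), right = FALSE)
  sf(times)
}

# ---- log-rank machinery ----------------------------------------------------

# risk/event structure shared by observed and permuted statistics
logrank_prepare <- function(time, status) {
  et <- sort(unique(time[status == 1]))
  if (length(et) == 0) return(NULL)
  n <- length(time)
  E <- outer(time, et, "==") * (status == 1)   # n x J event indicator
  R <- outer(time, et, ">=") * 1               # n x J at-risk indicator
  list(E = E, R = R, d = colSums(E), N = colSums(R))
}

# chi-square log-rank statistic for each row of a 0/1 group matrix G (B x n)
logrank_stat <- function(prep, G) {
  O1 <- G %*% prep$E
  N1 <- G %*% prep$R
  Nm <- matrix(prep$N, nrow(G), length(prep$N), byrow = TRUE)
  dm <- matrix(prep$d, nrow(G), length(prep$d), byrow = TRUE)
  E1 <- dm * N1 / Nm
  V <- dm * (N1 / Nm) * (1 - N1 / Nm) * ifelse(Nm > 1, (Nm - dm) / (Nm - 1), 0)
  num <- rowSums(O1 - E1)^2
  den <- rowSums(V)
  ifelse(den > 0, num / den, NA_real_)
}

#' Log-rank test between two survival groups
#'
#' Computes the standard one-degree-of-freedom log-rank statistic
#' \eqn{(\sum_j O_{1j} - E_{1j})^2 / \sum_j V_j} with the hypergeometric
#' variance at each distinct event time. The p-value comes from the
#' chi-square(1) upper tail, except in small samples where the statistic's
#' full permutation distribution over group assignments is enumerable: with
#' `method = "auto"` (default) the exact permutation p is used whenever
#' `choose(n, n_a) <= max_combinations`. The asymptotic chi-square p is
#' always reported alongside.
#'
#' @param records Tibble with `time`, `event` and a two-level `group` column.
#' @param method `"auto"`, `"chisq"` or `"exact"`.
#' @param max_combinations Enumeration cap for the automatic exact mode.
#' @return One-row tibble: `statistic`, `p` (selected method), `p_chisq`,
#'   `method_used`, `n_a`, `n_b`, `n_events`. `p` is `NA` when neither group
#'   has any event.
#' @export
logrank_test <- function(records, method = c("auto", "chisq", "exact"),
                         max_combinations = 20000) {
  method <- match.arg(method)
  assert_cols(records, c("time", "event", "group"))
  g <- as.factor(records$group)
  if (nlevels(g) != 2) stop_sp("logrank_test() needs exactly two groups")
  ga <- g == levels(g)[1]
  n_a <- sum(ga); n_b <- sum(!ga)
  if (n_a == 0 || n_b == 0) stop_sp("both groups must be non-empty")
  prep <- logrank_prepare(records$time, records$event)
  base <- tibble(statistic = NA_real_, p = NA_real_, p_chisq = NA_real_,
                 method_used = NA_character_, n_a = n_a, n_b = n_b,
                 n_events = sum(records$event))
  if (is.null(prep)) return(base)  # no events anywhere
  obs <- as.numeric(logrank_stat(prep, matrix(as.numeric(ga), nrow = 1)))
  if (is.na(obs)) return(base)
  p_chisq <- pchisq(obs, df = 1, lower.tail = FALSE)
  n <- n_a + n_b
  use_exact <- switch(method,
    chisq = FALSE,
    exact = TRUE,
    auto = choose(n, n_a) <= max_combinations
  )
  if (use_exact) {
    if (choose(n, n_a) > 5e5) stop_sp("exact log-rank: too many group assignments")
    combos <- utils::combn(n, n_a)
    G <- matrix(0, ncol(combos), n)
    G[cbind(rep(seq_len(ncol(combos)), each = n_a), as.vector(combos))] <- 1
    stats_perm <- logrank_stat(prep, G)
    p <- mean(stats_perm >= obs - 1e-12, na.rm = TRUE)
    method_used <- "exact"
  } else {
    p <- p_chisq
    method_used <- "chisq"
  }
  tibble(statistic = obs, p = p, p_chisq = p_chisq, method_used = method_used,
         n_a = n_a, n_b = n_b, n_events = sum(records$event))
}

#' Survival association screen over splicing events
#'
#' For each event, samples with a finite PSI and a survival record are
#' dichotomized at the median PSI (ties assigned to the low group) and the
#' two groups compared by log-rank. Events whose split is degenerate (all
#' samples on one side, e.g. constant PSI) get `logrank_p = NA`.
#'
#' @param psi Long PSI tibble.
#' @param survival Tibble `sample_id`, `time`, `event`.
#' @param min_overlap Minimum number of samples with both PSI and survival
#'   (default 4); fewer is an error.
#' @param method Passed to [logrank_test()].
#' @return Tibble: `event_id`, `logrank_p`, `statistic`, `n_high`, `n_low`,
#'   `group_rule`.
#' @export
survival_association <- function(psi, survival, min_overlap = 4,
                                 method = "auto") {
  assert_cols(psi, c("event_id", "sample_id", "psi"))
  assert_cols(survival, c("sample_id", "time", "event"))
  overlap <- intersect(unique(psi$sample_id), survival$sample_id)
  if (length(overlap) < min_overlap) {
    stop_sp("only ", length(overlap), " samples shared between PSI and ",
            "survival tables (need >= ", min_overlap, ")")
  }
  dat <- psi |>
    filter(!is.na(.data$psi)) |>
    inner_join(survival, by = "sample_id")
  all_events <- unique(psi$event_id)
  res <- dat |>
    group_by(.data$event_id) |>
    group_split() |>
    map(function(d) {
      med <- median(d$psi)
      high <- d$psi > med  # ties to the low group
      if (sum(high) == 0 || sum(!high) == 0 || nrow(d) < 2) {
        return(tibble(event_id = d$event_id[1], logrank_p = NA_real_,
                      statistic = NA_real_,
                      n_high = sum(high), n_low = sum(!high)))
      }
      lr <- logrank_test(tibble(time = d$time, event = d$event,
                                group = ifelse(high, "high", "low")),
                         method = method)
      tibble(event_id = d$event_id[1], logrank_p = lr$p,
             statistic = lr$statistic, n_high = sum(high), n_low = sum(!high))
    }) |>
    list_rbind()
  missing <- setdiff(all_events, res$event_id)
  if (length(missing) > 0) {
    res <- bind_rows(res, tibble(event_id = missing, logrank_p = NA_real_,
                                 statistic = NA_real_, n_high = 0L, n_low = 0L))
  }
  res |>
    mutate(group_rule = "median PSI split (ties low)") |>
    arrange(.data$event_id)
}
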