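# Stepwise term selection by partial-F probability, in the style of the
# classic stepwise linear-regression procedure: at each iteration the best
# excluded candidate enters if its partial-F p-value is at most p_enter, then
# included terms with p-value at least p_remove are removed one at a time.
#
# With p_enter > p_remove (the published settings are 0.5 and 0.10) the raw
# procedure can cycle: a term whose entry p-value lies between the two
# thresholds enters and is removed again indefinitely. Three guards give
# termination: a term that was just removed may not re-enter until some
# other term changes state; a state change that would revisit an earlier
# model state stops the search; and the loop is capped at
# 2 * (number of candidates)^2 state changes.

partial_f_p <- function(rss_small, rss_big, df_big) {
  # F for adding one column: (RSS0 - RSS1) / (RSS1 / df1), df = (1, df1)
  if (df_big <= 0) return(NA_real_)
  f <- (rss_small - rss_big) / (rss_big / df_big)
  stats::pf(max(f, 0), 1, df_big, lower.tail = FALSE)
}

fit_rss <- function(records, terms) {
  fit <- rsm_fit(records, terms)
  list(fit = fit, rss = sum(fit$residuals^2), df = fit$df.residual)
}

#' Stepwise response-surface selection by partial F probability
#'
#' Iteratively builds a model from `candidates`: the excluded term with the
#' smallest partial-F p-value is entered while that p-value is at most
#' `p_enter`; after each entry, included terms whose removal p-value is at
#' least `p_remove` are dropped (worst first). Ties on p-value are broken by
#' candidate order. Entry steps that would leave no residual degree of
#' freedom, or a rank-deficient design, are skipped. Termination is
#' guaranteed by a no-immediate-re-entry rule and a hard cap of
#' `2 * nrow(candidates)^2` state changes.
#'
#' With `p_enter > p_remove` (as in the defaults) the raw procedure can
#' oscillate — a term whose p-value falls between the thresholds enters and
#' is dropped again — so the search also stops the first time a model state
#' would repeat.
#'
#' @param records Data frame of factor columns plus `yield`.
#' @param candidates Candidate `rsm_terms` (default [candidate_terms()]).
#' @param p_enter Entry threshold on the partial-F p-value, in (0, 1);
#'   default 0.5.
#' @param p_remove Removal threshold, in (0, 1); default 0.10.
#' @return An `rsm_fit` for the selected terms, with a `steps` component
#'   recording the entry/removal path (labels prefixed `+`/`-`).
#' @examples
#' recs <- filter_records(phellinus45())
#' fit <- rsm_stepwise(recs)
#' coef(fit)
#' @export
rsm_stepwise <- function(records, candidates = candidate_terms(),
                         p_enter = 0.5, p_remove = 0.10) {
  stopifnot(p_enter > 0, p_enter < 1, p_remove > 0, p_remove < 1)
  nc <- nrow(candidates)
  included <- logical(nc)
  blocked <- logical(nc)   # removed, may not re-enter until state changes
  steps <- character(0)
  cap <- max(2L * nc^2, 10L)
  cur <- fit_rss(records, candidates[included, , drop = FALSE])
  seen <- paste(which(included), collapse = ",")

  try_fit <- function(idx) {
    tryCatch(fit_rss(records, candidates[idx, , drop = FALSE]),
             error = function(e) NULL)
  }
  revisits <- function(idx) {
    key <- paste(which(idx), collapse = ",")
    if (key %in% seen) return(TRUE)
    seen <<- c(seen, key)
    FALSE
  }

  changed <- TRUE
  while (changed && length(steps) < cap) {
    changed <- FALSE
    # entry: best admissible excluded candidate
    best_p <- Inf; best_k <- 0L; best_fit <- NULL
    for (k in which(!included & !blocked)) {
      idx <- included; idx[k] <- TRUE
      cand <- try_fit(idx)
      if (is.null(cand) || cand$df < 1L) next
      p <- partial_f_p(cur$rss, cand$rss, cand$df)
      if (is.finite(p) && p < best_p - 1e-15) {
        best_p <- p; best_k <- k; best_fit <- cand
      }
    }
    if (best_k > 0L && best_p <= p_enter) {
      trial <- included; trial[best_k] <- TRUE
      if (revisits(trial)) break
      included[best_k] <- TRUE
      blocked[] <- FALSE
      cur <- best_fit
      steps <- c(steps, paste0("+", candidates$label[best_k]))
      changed <- TRUE
    }
    # removal: drop worst included term while its p-value >= p_remove
    repeat {
      if (!any(included) || length(steps) >= cap) break
      worst_p <- -Inf; worst_k <- 0L; worst_fit <- NULL
      for (k in which(included)) {
        idx <- included; idx[k] <- FALSE
        red <- try_fit(idx)
        if (is.null(red)) next
        p <- partial_f_p(red$rss, cur$rss, cur$df)
        if (is.finite(p) && p > worst_p + 1e-15) {
          worst_p <- p; worst_k <- k; worst_fit <- red
        }
      }
      if (worst_k == 0L || worst_p < p_remove) break
      trial <- included; trial[worst_k] <- FALSE
      halt <- revisits(trial)   # dropping the oscillating term, then stop
      included[worst_k] <- FALSE
      blocked[] <- FALSE
      blocked[worst_k] <- TRUE
      cur <- worst_fit
      steps <- c(steps, paste0("-", candidates$label[worst_k]))
      changed <- !halt
      if (halt) break
    }
    if (!changed) break
  }
  fit <- cur$fit
  fit$steps <- steps
  fit
}
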