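#' Pooled z-scoring of session outcomes
#'
#' For each participant and outcome, values are z-scored against the pool of
#' all sessions and conditions of that participant (sample SD), so that
#' paired contrasts compare standardised values and effect sizes are
#' commensurable across outcome measures.
#'
#' @param table Data frame with columns `participant`, `condition`,
#'   `session`, `outcome`, `value`.
#' @return The table with an added `z` column; participants with fewer than
#'   two values or zero spread for an outcome get `NA`.
#' @export
zscore_outcomes <- function(table) {
  need <- c("participant", "condition", "session", "outcome", "value")
  stopifnot(all(need %in% names(table)))
  key <- interaction(table$participant, table$outcome, drop = TRUE)
  table$z <- NA_real_
  for (k in levels(key)) {
    idx <- which(key == k)
    v <- table$value[idx]
    if (sum(!is.na(v)) >= 2L) {
      s <- stats::sd(v, na.rm = TRUE)
      if (is.finite(s) && s > 0)
        table$z[idx] <- (v - mean(v, na.rm = TRUE)) / s
    }
  }
  table
}

# Hedges small-sample correction factor
.hedges_J <- function(df) 1 - 3 / (4 * df - 1)

#' Paired t-test with Hedges' g
#'
#' Classical two-sided paired t-test on pairwise-complete observations, with
#' the standardised mean difference of the paired differences corrected for
#' small samples: `g = J * mean(d)/sd(d)`, `J = 1 - 3/(4*df - 1)`,
#' `df = n - 1`.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return Object of class `paired_test`: list with `t`, `df`, `p`, `g`,
#'   `n`, `mean_diff`. When the difference spread is zero the test is
#'   degenerate: `t`, `p`, `g` are `NA` and `degenerate` is `TRUE`.
#' @export
paired_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) stop("need at least 2 complete pairs")
  d <- x - y
  sd_d <- stats::sd(d)
  if (!is.finite(sd_d) || sd_d == 0) {
    return(structure(list(t = NA_real_, df = n - 1L, p = NA_real_,
                          g = if (all(d == 0)) 0 else NA_real_, n = n,
                          mean_diff = mean(d), degenerate = TRUE),
                     class = "paired_test"))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  g <- .hedges_J(n - 1L) * mean(d) / sd_d
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, g = g, n = n, mean_diff = mean(d),
                 degenerate = FALSE),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("paired t-test: degenerate (zero difference spread), n = %d\n",
                x$n))
  } else {
    cat(sprintf("paired t(%d) = %.3f, p = %.4g, Hedges' g = %.3f (n = %d)\n",
                x$df, x$t, x$p, x$g, x$n))
  }
  invisible(x)
}

#' Default wake-session clock schedule
#'
#' Decimal clock hours of the eight wake recordings; sessions after midnight
#' are placed on a continuous next-day axis (+24 h) so that 02:40 follows
#' 23:00.
#'
#' @return Named numeric vector of decimal hours for S1..S8.
#' @export
session_schedule <- function() {
  c(S1 = 3, S2 = 7, S3 = 10.5, S4 = 14, S5 = 17.5, S6 = 20, S7 = 23,
    S8 = 24 + 2 + 40 / 60)
}

#' Wake-maintenance-zone interpolation contrast
#'
#' The WMZ (1-4 h before habitual bedtime) shows up as a dip in otherwise
#' monotonically rising sleep-pressure markers. The contrast linearly
#' interpolates each participant's S5 (17:30) and S8 (02:40, next day) values
#' at the 21:30 target time and subtracts that expectation from the observed
#' mean of S6 (20:00) and S7 (23:00); the group test is a paired t of
#' observed versus expected.
#'
#' @param values Numeric matrix or data frame, participants in rows, columns
#'   named `S5`, `S6`, `S7`, `S8` (z-scored outcome values).
#' @param times Named clock times in decimal hours; defaults to the S5-S8
#'   entries of [session_schedule()].
#' @param target_h Interpolation target in decimal hours (default 21.5).
#' @return List with `statistic` (per-participant observed - expected),
#'   `expected`, `observed`, `weight` (interpolation weight of S8) and
#'   `test` (a [paired_test()] of observed vs expected). Participants with a
#'   missing session are dropped.
#' @export
wmz_contrast <- function(values, times = session_schedule()[c("S5", "S6",
                                                              "S7", "S8")],
                         target_h = 21.5) {
  values <- as.data.frame(values)
  stopifnot(all(c("S5", "S6", "S7", "S8") %in% names(values)))
  keep <- stats::complete.cases(values[, c("S5", "S6", "S7", "S8")])
  v <- values[keep, , drop = FALSE]
  w <- (target_h - times[["S5"]]) / (times[["S8"]] - times[["S5"]])
  expected <- v$S5 + w * (v$S8 - v$S5)
  observed <- (v$S6 + v$S7) / 2
  list(statistic = observed - expected, expected = expected,
       observed = observed, weight = w,
       n_dropped = sum(!keep),
       test = if (sum(keep) >= 2L) paired_test(observed, expected) else NULL)
}

#' Benjamini-Hochberg false-discovery-rate rejection set
#'
#' Step-up procedure at level `q`; used for channelwise t-test maps (123
#' channels), not for the session-level battery.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical rejection vector aligned with `p`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH") <= q
}

#' Minimum detectable effect size of a paired t-test
#'
#' Inverts the noncentral-t power function of the two-sided paired t-test
#' (via [stats::power.t.test()]) for the smallest standardised difference
#' with the requested power, and converts Cohen's d to Hedges' g with the
#' small-sample correction.
#'
#' @param n Number of pairs (>= 2).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @return Minimum detectable Hedges' g.
#' @examples
#' min_detectable_g(18)  # about 0.67
#' @export
min_detectable_g <- function(n, alpha = 0.05, power = 0.8) {
  stopifnot(n >= 2)
  d <- stats::power.t.test(n = n, sig.level = alpha, power = power,
                           type = "paired",
                           alternative = "two.sided")$delta
  .hedges_J(n - 1) * d
}

#' Session-level statistics battery
#'
#' Runs the three standard paired contrasts on a long outcome table:
#' wake-dependent change (S1 vs S8), sleep-dependent change (BL_pre vs
#' BL_post) and the WMZ interpolation contrast, per outcome and condition,
#' on pooled-z-scored values.
#'
#' @param table Long data frame (`participant`, `condition`, `session`,
#'   `outcome`, `value`); z-scoring is applied internally via
#'   [zscore_outcomes()].
#' @param contrasts Which of `"wake"`, `"sleep"`, `"wmz"` to run.
#' @return Data frame mirroring a results table: `outcome`, `condition`,
#'   `contrast`, `t`, `df`, `p`, `g`.
#' @export
session_battery <- function(table, contrasts = c("wake", "sleep", "wmz")) {
  tz <- zscore_outcomes(table)
  out <- list()
  wide_of <- function(sub) {
    stats::reshape(sub[, c("participant", "session", "z")],
                   idvar = "participant", timevar = "session",
                   direction = "wide")
  }
  for (oc in unique(tz$outcome)) {
    for (cond in unique(tz$condition)) {
      sub <- tz[tz$outcome == oc & tz$condition == cond, , drop = FALSE]
      if (nrow(sub) == 0L) next
      w <- wide_of(sub)
      names(w) <- sub("^z\\.", "", names(w))
      add <- function(contrast, ht) {
        if (is.null(ht)) return()
        out[[length(out) + 1L]] <<- data.frame(
          outcome = oc, condition = cond, contrast = contrast,
          t = ht$t, df = ht$df, p = ht$p, g = ht$g)
      }
      if ("wake" %in% contrasts && all(c("S1", "S8") %in% names(w))) {
        cc <- stats::complete.cases(w$S1, w$S8)
        if (sum(cc) >= 2) add("S8-S1", paired_test(w$S8[cc], w$S1[cc]))
      }
      if ("sleep" %in% contrasts &&
          all(c("BL_pre", "BL_post") %in% names(w))) {
        cc <- stats::complete.cases(w$BL_pre, w$BL_post)
        if (sum(cc) >= 2)
          add("BLpost-BLpre", paired_test(w$BL_post[cc], w$BL_pre[cc]))
      }
      if ("wmz" %in% contrasts && all(c("S5", "S6", "S7", "S8") %in%
                                      names(w))) {
        wc <- wmz_contrast(w)
        add("WMZ", wc$test)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(outcome = character(), condition = character(),
               contrast = character(), t = numeric(), df = numeric(),
               p = numeric(), g = numeric())
}
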