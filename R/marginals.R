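# Published marginal selection percentages and their reconstruction into
# integer counts and synthetic per-participant selection matrices.

#' Packaged marginal tables
#'
#' Cell-for-cell transcriptions of the published percentage tables: action
#' choice and emotion choice for the three Actor Studio scenarios, and
#' emotion choice for the main and other character of the four Audience
#' Studio scenarios. Dashes in the source are stored as 0.0 and every cell
#' carries a provenance string. The other-character table is flagged
#' provisional (its source layout is partly ambiguous) and is never used as
#' an acceptance reference.
#'
#' @param table One of `"actor_actions"`, `"actor_emotions"`,
#'   `"audience_main"`, `"audience_other"`.
#' @return A data frame with columns `scenario`, `group`, `plan`/`emotion`,
#'   `predicted`, `pct`, `source` (plus `provisional` where applicable).
#' @export
#' @examples
#' head(load_marginals("actor_emotions"))
load_marginals <- function(table = c("actor_emotions", "actor_actions",
                                     "audience_main", "audience_other")) {
  table <- match.arg(table)
  path <- system.file("extdata", "marginals", paste0(table, ".csv"),
                      package = "meagent")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Group sizes of the Actor Studio analysis
#'
#' @return Named integer vector: 13 participants in the TBI group, 11
#'   controls.
#' @export
group_sizes <- function() c(TBI = 13L, control = 11L)

#' Reconstruct a selection count from a printed percentage
#'
#' Percentages in the source are `100 k / n` rounded to one decimal, so for
#' the study's group sizes the count is recovered exactly as
#' `k = round(pct * n / 100)`. The residual `|100 k / n - pct|` must not
#' exceed `tol` (default 0.06: strict one-decimal rounding gives at most
#' 0.05, with a small margin for the source's inconsistent rounding);
#' otherwise the cell is reported as inconsistent.
#'
#' @param pct Printed percentage in \[0, 100\] (vectorized).
#' @param n Group size, 1..30.
#' @param tol Residual tolerance in percentage points.
#' @param cell Optional label(s) used in the inconsistency error message.
#' @return Integer count(s) `k`.
#' @export
#' @examples
#' pct_to_count(46.2, 13)  # 6 of 13
pct_to_count <- function(pct, n, tol = 0.06, cell = NULL) {
  stopifnot(all(pct >= 0), all(pct <= 100), n >= 1, n <= 30)
  k <- as.integer(round(pct * n / 100))
  resid <- abs(100 * k / n - pct)
  if (any(resid > tol)) {
    i <- which(resid > tol)[1]
    lab <- if (!is.null(cell)) cell[min(i, length(cell))] else
      paste0("pct=", pct[i], ", n=", n)
    stop("percentage inconsistent with group size (residual ",
         format(round(resid[i], 3)), " > ", tol, ") at ", lab, call. = FALSE)
  }
  k
}

#' Infer the per-scenario group size from its percentages
#'
#' The Audience Studio per-scenario sample sizes are not printed (sessions
#' were split); they are recovered as the smallest `n <= n_max` under which
#' every non-zero percentage is consistent with some integer count.
#'
#' @param pcts Numeric vector of printed percentages (zeros are ignored —
#'   they are consistent with any `n`).
#' @param n_max Largest size considered.
#' @param tol Residual tolerance, as in [pct_to_count()].
#' @return The inferred group size.
#' @export
#' @examples
#' infer_group_size(c(37.5, 25, 50, 87.5, 75, 62.5))  # 8
infer_group_size <- function(pcts, n_max = 30L, tol = 0.06) {
  pcts <- pcts[pcts > 0]
  if (length(pcts) == 0L) {
    stop("cannot infer a group size from all-zero percentages", call. = FALSE)
  }
  for (n in seq_len(n_max)) {
    ok <- vapply(pcts, function(p) {
      k <- round(p * n / 100)
      abs(100 * k / n - p) <= tol
    }, logical(1))
    if (all(ok)) return(as.integer(n))
  }
  stop("no group size up to ", n_max, " is consistent with the percentages",
       call. = FALSE)
}

#' Marginals with reconstructed integer counts
#'
#' Adds the group size `n` (fixed for the Actor Studio, inferred per
#' scenario and group for the Audience Studio) and the reconstructed count
#' `k` to a packaged marginal table.
#'
#' @inheritParams load_marginals
#' @return The marginal data frame with extra columns `n` and `k`.
#' @export
marginal_counts <- function(table = c("actor_emotions", "actor_actions",
                                      "audience_main", "audience_other")) {
  table <- match.arg(table)
  df <- load_marginals(table)
  if (startsWith(table, "actor")) {
    df$n <- group_sizes()[df$group]
  } else {
    df$n <- NA_integer_
    for (sc in unique(df$scenario)) {
      for (gr in unique(df$group)) {
        i <- df$scenario == sc & df$group == gr
        df$n[i] <- infer_group_size(df$pct[i])
      }
    }
  }
  df$k <- as.integer(mapply(function(p, n, s) pct_to_count(p, n, cell = s),
                            df$pct, df$n, df$source))
  df
}

#' Generate a synthetic respondent selection matrix
#'
#' The per-participant joint selections behind the published tables are
#' unavailable; this generates a binary n x 12 stand-in consistent with the
#' marginals. In `exact_marginal` mode each emotion column receives exactly
#' its reconstructed count of 1s, placed by a seeded permutation, so every
#' statistic that is linear in the column sums is reproduced exactly and is
#' seed-invariant. In `bernoulli` mode entries are i.i.d. with p = k/n.
#'
#' @param marginals Data frame with columns `emotion` and `k` (and
#'   optionally `n`), e.g. one scenario-group slice of
#'   [marginal_counts()]`("actor_emotions")`.
#' @param n Number of respondents (defaults to the `n` column).
#' @param mode `"exact_marginal"` or `"bernoulli"`.
#' @param seed Integer seed.
#' @return Binary matrix with `n` rows and one column per emotion type, in
#'   the published column order.
#' @export
generate_respondents <- function(marginals, n = NULL,
                                 mode = c("exact_marginal", "bernoulli"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  n <- n %||% marginals$n[1]
  stopifnot(!is.null(n), n >= 1)
  k <- stats::setNames(marginals$k, marginals$emotion)[emotion_types()]
  if (anyNA(k)) stop("marginals must cover all 12 emotions", call. = FALSE)
  if (any(k > n)) stop("count exceeds group size", call. = FALSE)
  m <- matrix(0L, nrow = n, ncol = length(k),
              dimnames = list(NULL, emotion_types()))
  with_local_seed(seed, {
    for (j in seq_along(k)) {
      if (mode == "exact_marginal") {
        if (k[j] > 0) m[sample.int(n, k[j]), j] <- 1L
      } else {
        m[, j] <- stats::rbinom(n, 1L, k[j] / n)
      }
    }
  })
  m
}

#' Write a selection matrix to CSV
#'
#' Header row carries the 12 emotion names in the published column order.
#'
#' @param m Matrix from [generate_respondents()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}
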