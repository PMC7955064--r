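# Evaluation arithmetic on affinity-measured candidate sets: group summary
# statistics, fold-improvement over the parental clone, and the
# NLL-vs-affinity regression.

#' Read the bundled evaluated-sequences table
#'
#' Twenty-one anti-kynurenine antibodies: ten candidates prioritized by
#' model likelihood (`ML`), ten by NGS read frequency (`Freq`), and the
#' parental clone (`Control`). Columns: `group`, `vector` (the 17
#' diversified residues), `nll` (NA for the parent), `kd_molar`
#' (SPR dissociation constant, molar).
#'
#' @param path Fixture path (defaults to the bundled table).
#' @return `data.frame` with 21 rows.
#' @export
read_affinity_table <- function(path = system.file("extdata", "table3.tsv",
                                                   package = "phagelm",
                                                   mustWork = TRUE)) {
  df <- read.delim(path, colClasses = c(vector = "character"))
  stopifnot(all(c("group", "vector", "nll", "kd_molar") %in% names(df)),
            all(df$kd_molar > 0))
  df
}

#' Summary statistics of one candidate group's affinities
#'
#' Median, lower and upper quartiles and the best (smallest) dissociation
#' constant. The median of an even-sized group is the mean of the two
#' central order statistics; quartiles use the inclusive
#' linear-interpolation convention (R quantile type 7), configurable via
#' `type`.
#'
#' @param records Affinity table from [read_affinity_table()].
#' @param group Group name present in `records$group`.
#' @param type Quantile type passed to [stats::quantile()].
#' @return Named list: `median`, `q1`, `q3`, `min`, `n`.
#' @export
group_stats <- function(records, group, type = 7) {
  if (!group %in% records$group)
    stop("unknown group '", group, "'")
  kd <- records$kd_molar[records$group == group]
  q <- quantile(kd, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], min = min(kd), n = length(kd))
}

#' Fold improvement of the best model-derived candidate over the parent
#'
#' Ratio of the parental clone's dissociation constant to the smallest
#' dissociation constant in the `ML` group (larger = better improvement);
#' invariant to the unit K_D is expressed in.
#'
#' @param records Affinity table with `Control` and `ML` groups.
#' @return Positive scalar.
#' @export
fold_improvement <- function(records) {
  if (!"Control" %in% records$group) stop("Control record missing")
  kd_parent <- records$kd_molar[records$group == "Control"][1]
  kd_best <- min(records$kd_molar[records$group == "ML"])
  kd_parent / kd_best
}

#' Regression of affinity on model likelihood
#'
#' Ordinary least squares of `log10(kd)` on NLL over all records carrying
#' both values, plus the fraction of candidates binding tighter than the
#' parental clone within NLL bins (default: below 15, 15 to 20, 20 and
#' above).
#'
#' @param records Affinity table; rows with `NA` NLL are ignored for the
#'   fit.
#' @param breaks Interior NLL bin edges (default `c(15, 20)`).
#' @return List: `r_squared`, `slope`, `intercept`, `n`, and
#'   `better_than_parent` (data.frame with bin label, n, n_better,
#'   fraction). `r_squared` is `NA` with a warning when NLL has zero
#'   variance.
#' @export
nll_affinity_fit <- function(records, breaks = c(15, 20)) {
  df <- records[!is.na(records$nll), , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 records with NLL and kd")
  out <- list()
  if (var(df$nll) == 0) {
    warning("NLL has zero variance; R^2 undefined")
    out$r_squared <- NA_real_
    out$slope <- NA_real_
    out$intercept <- NA_real_
  } else {
    fit <- lm(log10(kd_molar) ~ nll, data = df)
    out$r_squared <- summary(fit)$r.squared
    out$slope <- unname(coef(fit)[2])
    out$intercept <- unname(coef(fit)[1])
  }
  out$n <- nrow(df)
  kd_parent <- if ("Control" %in% records$group)
    records$kd_molar[records$group == "Control"][1] else NA_real_
  edges <- c(-Inf, breaks, Inf)
  lab <- character(length(edges) - 1)
  for (i in seq_along(lab)) {
    lab[i] <- if (i == 1) sprintf("NLL < %g", edges[2])
    else if (i == length(lab)) sprintf("NLL >= %g", edges[i])
    else sprintf("%g <= NLL < %g", edges[i], edges[i + 1])
  }
  bin <- cut(df$nll, edges, right = FALSE, labels = lab)
  btp <- do.call(rbind, lapply(levels(bin), function(bl) {
    sel <- bin == bl
    data.frame(bin = bl, n = sum(sel),
               n_better = sum(df$kd_molar[sel] < kd_parent),
               fraction = if (any(sel))
                 mean(df$kd_molar[sel] < kd_parent) else NA_real_)
  }))
  out$better_than_parent <- btp
  out
}
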