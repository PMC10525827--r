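#' Fit the repeated-measures interval-sum model
#'
#' Fits a linear mixed model to windowed interval sums of one kinematic
#' parameter: response = interval sum, fixed effects = one cell mean per
#' stimulus x interval combination (the analysis cells are the baseline
#' "BL" slot and the four post-stimulus intervals of each stimulus), and
#' a random intercept per embryo to account for the repeated measures.
#' Estimation is REML via \pkg{lme4}. Excluded intervals must already be
#' absent from (or NA in) the table; NA sums are dropped.
#'
#' The study this pipeline supports used a robust (Huberized) mixed
#' model; here the standard REML fit is paired with the distribution-free
#' [permutation_contrast] as the robust companion route.
#'
#' @param data data.frame with columns `embryo_id`, `stimulus`,
#'   `interval`, `sum` (one kinematic parameter; rows with `interval =
#'   "BL"` carry the baseline statistic). An `interval_summary` table
#'   restricted to one parameter works directly provided an `embryo_id`
#'   column is present (use `trial_id` via `embryo_id`).
#' @param cells optional character vector restricting which intervals
#'   enter the model; default `c("BL", "0-30", "30-60", "60-90",
#'   "90-120")`.
#' @return an object of class `interval_lmm` with `print`, `summary`,
#'   `coef`, `plot` and [marginal_contrasts] methods.
#' @export
fit_interval_model <- function(data,
                               cells = c("BL", "0-30", "30-60", "60-90", "90-120")) {
  data <- as.data.frame(data)
  if (!"embryo_id" %in% names(data) && "trial_id" %in% names(data))
    data$embryo_id <- data$trial_id
  need <- c("embryo_id", "stimulus", "interval", "sum")
  if (!all(need %in% names(data)))
    stop("fit_interval_model: data needs columns ", paste(need, collapse = ", "))
  if ("parameter" %in% names(data) && length(unique(data$parameter)) > 1)
    stop("fit_interval_model: fit one parameter at a time")
  d <- data[data$interval %in% cells & !is.na(data$sum), , drop = FALSE]
  if ("excluded" %in% names(d)) d <- d[!d$excluded, , drop = FALSE]
  d$cell <- factor(paste(d$stimulus, d$interval, sep = ":"))
  d$embryo_id <- factor(d$embryo_id)
  if (nlevels(d$embryo_id) < 2)
    stop("fit_interval_model: degenerate design - at least 2 embryos are required ",
         "to separate the embryo random effect from the residual")
  fit <- lme4::lmer(sum ~ 0 + cell + (1 | embryo_id), data = d, REML = TRUE)
  structure(list(fit = fit, data = d, cells = levels(d$cell),
                 parameter = if ("parameter" %in% names(d)) d$parameter[1] else NA),
            class = "interval_lmm")
}

#' @method print interval_lmm
#' @export
print.interval_lmm <- function(x, ...) {
  cat("<interval_lmm> repeated-measures interval-sum model\n")
  if (!is.na(x$parameter)) cat("  parameter:", x$parameter, "\n")
  cat(sprintf("  %d observations, %d embryos, %d cells\n",
              nrow(x$data), nlevels(x$data$embryo_id), length(x$cells)))
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  cat(sprintf("  embryo SD %.4g, residual SD %.4g\n",
              vc$sdcor[vc$grp == "embryo_id"], vc$sdcor[vc$grp == "Residual"]))
  invisible(x)
}

#' @method coef interval_lmm
#' @export
coef.interval_lmm <- function(object, ...) {
  b <- lme4::fixef(object$fit)
  names(b) <- sub("^cell", "", names(b))
  b
}

#' @method summary interval_lmm
#' @export
summary.interval_lmm <- function(object, ...) {
  emm <- emmeans::emmeans(object$fit, "cell", lmer.df = "satterthwaite")
  s <- as.data.frame(emm)
  names(s)[1] <- "cell"
  vc <- as.data.frame(lme4::VarCorr(object$fit))
  structure(list(cells = s,
                 sd_embryo = vc$sdcor[vc$grp == "embryo_id"],
                 sd_residual = vc$sdcor[vc$grp == "Residual"],
                 n_embryos = nlevels(object$data$embryo_id)),
            class = "summary.interval_lmm")
}

#' @method print summary.interval_lmm
#' @export
print.summary.interval_lmm <- function(x, ...) {
  cat("Estimated cell means (interval sums):\n")
  print(x$cells, row.names = FALSE)
  cat(sprintf("\nRandom effects: embryo SD %.4g, residual SD %.4g (%d embryos)\n",
              x$sd_embryo, x$sd_residual, x$n_embryos))
  invisible(x)
}

#' @method plot interval_lmm
#' @export
plot.interval_lmm <- function(x, ...) {
  s <- summary(x)$cells
  parts <- do.call(rbind, strsplit(as.character(s$cell), ":", fixed = TRUE))
  ord <- c("BL", "0-30", "30-60", "60-90", "90-120")
  s$stimulus <- parts[, 1]
  s$pos <- match(parts[, 2], ord)
  graphics::plot(NA, xlim = c(1, length(ord)), ylim = range(s$lower.CL, s$upper.CL),
                 xaxt = "n", xlab = "interval", ylab = "interval sum",
                 main = if (!is.na(x$parameter)) x$parameter else "interval sums", ...)
  graphics::axis(1, at = seq_along(ord), labels = ord)
  for (st in unique(s$stimulus)) {
    ss <- s[s$stimulus == st, ]
    ss <- ss[order(ss$pos), ]
    col <- if (st == "Pinch") "red3" else "steelblue"
    graphics::lines(ss$pos, ss$emmean, col = col, type = "b", pch = 16)
    graphics::arrows(ss$pos, ss$lower.CL, ss$pos, ss$upper.CL,
                     angle = 90, code = 3, length = 0.04, col = col)
  }
  graphics::legend("topright", legend = unique(s$stimulus), col =
                     ifelse(unique(s$stimulus) == "Pinch", "red3", "steelblue"),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Default contrast family
#'
#' The comparisons mirrored from the study's figures, per parameter: each
#' post-stimulus interval of a stimulus against that stimulus's baseline,
#' and Pinch against Touch at each post-stimulus interval.
#'
#' @param intervals post-stimulus interval labels.
#' @return list of length-2 character vectors (cell pairs).
#' @export
default_contrasts <- function(intervals = c("0-30", "30-60", "60-90", "90-120")) {
  out <- list()
  for (iv in intervals) {
    out[[paste0("Pinch ", iv, " vs Pinch BL")]] <- c(paste0("Pinch:", iv), "Pinch:BL")
    out[[paste0("Touch ", iv, " vs Touch BL")]] <- c(paste0("Touch:", iv), "Touch:BL")
    out[[paste0("Pinch ", iv, " vs Touch ", iv)]] <- c(paste0("Pinch:", iv), paste0("Touch:", iv))
  }
  out
}

#' Marginal-mean contrasts with family-wise adjustment
#'
#' Pairwise differences of estimated marginal (cell) means from a fitted
#' [fit_interval_model], adjusted over the declared comparison family
#' with the multivariate-t method (the exact Tukey-style adjustment for
#' an arbitrary set of contrasts). A single-comparison family gets an
#' adjusted p equal to the unadjusted p.
#'
#' @param object an `interval_lmm`.
#' @param comparisons list of length-2 character vectors naming cell
#'   pairs, e.g. `list(c("Pinch:0-30", "Pinch:BL"))`; default
#'   [default_contrasts] restricted to cells present in the model.
#' @param alpha significance level (default 0.05).
#' @param adjust multiplicity adjustment passed to \pkg{emmeans}
#'   (default "mvt").
#' @return data.frame with columns `comparison`, `estimate`, `SE`, `df`,
#'   `p_value` (unadjusted), `p_adjusted`, `significant`.
#' @export
marginal_contrasts <- function(object, comparisons = NULL, alpha = 0.05,
                               adjust = "mvt") {
  stopifnot(inherits(object, "interval_lmm"))
  cells <- object$cells
  if (is.null(comparisons)) {
    comparisons <- Filter(function(p) all(p %in% cells), default_contrasts())
    if (!length(comparisons))
      stop("marginal_contrasts: no default comparison is estimable from the model cells")
  }
  for (nm in seq_along(comparisons)) {
    p <- comparisons[[nm]]
    miss <- setdiff(p, cells)
    if (length(miss))
      stop("marginal_contrasts: cell(s) not in model: ", paste(miss, collapse = ", "))
  }
  if (is.null(names(comparisons)))
    names(comparisons) <- vapply(comparisons, paste, "", collapse = " vs ")
  emm <- emmeans::emmeans(object$fit, "cell", lmer.df = "satterthwaite")
  lev <- as.data.frame(emm)$cell
  meth <- lapply(comparisons, function(p) {
    v <- numeric(length(lev))
    v[lev == p[1]] <- 1; v[lev == p[2]] <- -1
    v
  })
  adj <- as.data.frame(emmeans::contrast(emm, method = meth, adjust = adjust))
  raw <- as.data.frame(emmeans::contrast(emm, method = meth, adjust = "none"))
  out <- data.frame(comparison = names(comparisons),
                    estimate = adj$estimate, SE = adj$SE, df = adj$df,
                    p_value = raw$p.value,
                    p_adjusted = pmax(adj$p.value, raw$p.value))
  out$significant <- out$p_adjusted < alpha
  out
}

#' Paired sign-flip permutation contrast
#'
#' Distribution-free within-embryo contrast of two analysis cells: for
#' every embryo with both cells observed, the difference of interval sums
#' is formed; the observed statistic is the paired t statistic of those
#' differences, and its null distribution is generated by random sign
#' flips of the embryo-level differences. p = (1 + #\{|T_perm| >=
#' |T_obs|\}) / (1 + n_perm). With `comparisons` a list, the same flips
#' are shared across the family and max-T over the family yields
#' family-wise adjusted p values.
#'
#' @param data interval table as for [fit_interval_model].
#' @param comparison length-2 character vector of cells, e.g.
#'   `c("Pinch:0-30", "Pinch:BL")`; or a named list of such pairs.
#' @param n_perm number of sign-flip draws (>= 100).
#' @param seed optional integer seed for the flips.
#' @return for a single comparison, a list with `p`, `statistic`,
#'   `estimate` (mean difference) and `n` (paired embryos); for a family,
#'   a data.frame with unadjusted `p_value` and max-T `p_adjusted`.
#' @export
permutation_contrast <- function(data, comparison, n_perm = 1000, seed = NULL) {
  if (n_perm < 100)
    stop("permutation_contrast: n_perm must be at least 100")
  single <- !is.list(comparison)
  comps <- if (single) list(comparison) else comparison
  if (is.null(names(comps)))
    names(comps) <- vapply(comps, paste, "", collapse = " vs ")
  data <- as.data.frame(data)
  if (!"embryo_id" %in% names(data) && "trial_id" %in% names(data))
    data$embryo_id <- data$trial_id
  data$cell <- paste(data$stimulus, data$interval, sep = ":")
  dmat <- sapply(comps, function(p) {
    a <- data[data$cell == p[1], c("embryo_id", "sum")]
    b <- data[data$cell == p[2], c("embryo_id", "sum")]
    m <- merge(a, b, by = "embryo_id")
    m <- m[stats::complete.cases(m), ]
    d <- m$sum.x - m$sum.y
    names(d) <- m$embryo_id
    d
  }, simplify = FALSE)
  ids <- Reduce(intersect, lapply(dmat, names))
  if (length(ids) < 2)
    stop("permutation_contrast: fewer than 2 embryos with both cells observed")
  D <- sapply(dmat, function(d) d[ids])  # embryos x comparisons
  if (is.null(dim(D))) D <- matrix(D, ncol = length(comps))
  n <- length(ids)
  tstat <- function(d) {
    s <- stats::sd(d)
    if (s == 0) { if (mean(d) == 0) 0 else sign(mean(d)) * Inf }
    else mean(d) / (s / sqrt(n))
  }
  t_obs <- apply(D, 2, tstat)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  # sign flips leave sum(d^2) unchanged, so only the flipped mean is needed
  t_perm <- matrix(0, n_perm, ncol(D))
  for (j in seq_len(ncol(D))) {
    m <- as.vector(signs %*% D[, j]) / n
    v <- pmax(0, (sum(D[, j]^2) - n * m^2) / (n - 1))
    tj <- ifelse(v == 0, ifelse(m == 0, 0, sign(m) * Inf), m / sqrt(v / n))
    t_perm[, j] <- tj
  }
  # tolerance on the tie comparison so affine rescaling of the response
  # cannot flip an exact-equality permutation (e.g. the identity flip)
  thr <- function(t) abs(t) - 1e-8 * (1 + abs(t))
  p_raw <- vapply(seq_len(ncol(D)), function(j)
    (1 + sum(abs(t_perm[, j]) >= thr(t_obs[j]))) / (1 + n_perm), 0)
  if (single) {
    return(list(p = p_raw[1], statistic = t_obs[[1]],
                estimate = mean(D[, 1]), n = n))
  }
  maxT <- apply(abs(t_perm), 1, max)
  p_adj <- vapply(seq_len(ncol(D)), function(j)
    (1 + sum(maxT >= thr(t_obs[j]))) / (1 + n_perm), 0)
  data.frame(comparison = names(comps),
             estimate = colMeans(D), statistic = unname(t_obs),
             n = n, p_value = p_raw, p_adjusted = pmax(p_adj, p_raw))
}
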