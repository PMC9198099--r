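#' Parameters for the co-selection cohort simulator
#'
#' The simulator formalises phenotype-based co-selection in mosaic injected
#' embryos: each embryo receives a latent editing dose (how much active
#' editor/guide it got), drawn from a Beta distribution, and each locus
#' responds through a logistic link \code{plogis(intercept + slope * dose)}
#' giving its expected edit fraction. In \code{"shared-dose"} mode one dose
#' drives all loci (inducing positive inter-locus correlation, the premise
#' of co-selection); in \code{"independent"} mode each locus draws its own
#' dose, breaking the correlation. Embryos are binned into the four
#' pigmentation groups (wt-like, mild, severe, albino) by thresholding the
#' selection-locus edit fraction.
#'
#' @param nEmbryos Number of embryos.
#' @param doseAlpha,doseBeta Beta parameters of the dose distribution.
#' @param loci data.frame with columns \code{locus}, \code{intercept},
#'   \code{slope} (logit scale).
#' @param selection Name of the selection (pigmentation) locus.
#' @param mode \code{"shared-dose"} or \code{"independent"}.
#' @param thresholds Increasing cutpoints in (0,1) on the selection-locus
#'   fraction defining the four phenotype groups.
#' @param dispersion Beta concentration of per-embryo scatter around the
#'   link mean; \code{Inf} makes fractions deterministic in the dose.
#' @param seed Integer seed.
#' @return A validated parameter list (class \code{CohortParams}).
#' @export
cohortParams <- function(nEmbryos = 100L,
                         doseAlpha = 2, doseBeta = 2,
                         loci = data.frame(
                           locus = c("tyr", "nras", "rb1"),
                           intercept = c(-2, -1.5, -3),
                           slope = c(6, 5, 4),
                           stringsAsFactors = FALSE),
                         selection = "tyr",
                         mode = c("shared-dose", "independent"),
                         thresholds = c(0.25, 0.6, 0.9),
                         dispersion = 20,
                         seed = 1L) {
  mode <- match.arg(mode)
  nEmbryos <- .assert_scalar_int(nEmbryos, "nEmbryos", 1L)
  if (doseAlpha <= 0 || doseBeta <= 0)
    stop("dose Beta parameters must be positive", call. = FALSE)
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0) ||
      any(thresholds <= 0) || any(thresholds >= 1))
    stop("thresholds must be three increasing values in (0, 1)",
         call. = FALSE)
  if (!selection %in% loci$locus)
    stop("selection locus '", selection, "' not in loci table",
         call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  structure(list(nEmbryos = nEmbryos, doseAlpha = doseAlpha,
                 doseBeta = doseBeta, loci = loci, selection = selection,
                 mode = mode, thresholds = thresholds,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "CohortParams")
}

PHENOTYPE_GROUPS <- c("wt-like", "mild", "severe", "albino")

#' Simulated or observed co-selection cohort
#'
#' @slot embryos data.frame with \code{embryo_id}, \code{dose},
#'   \code{group} (ordered factor wt-like < mild < severe < albino).
#' @slot fractions Numeric matrix embryos x loci of edit fractions in
#'   [0, 1].
#' @slot selection Selection locus name.
#' @slot thresholds Group cutpoints used.
#' @export
setClass("Cohort",
  representation(embryos = "data.frame", fractions = "matrix",
                 selection = "character", thresholds = "numeric"))

setValidity("Cohort", function(object) {
  msg <- character(0)
  f <- object@fractions
  if (nrow(object@embryos) != nrow(f))
    msg <- c(msg, "embryos and fractions disagree on n")
  if (any(f < 0) || any(f > 1))
    msg <- c(msg, "edit fractions must lie in [0, 1]")
  if (!object@selection %in% colnames(f))
    msg <- c(msg, "selection locus missing from fractions")
  else {
    grp <- cut(f[, object@selection],
               c(-Inf, object@thresholds, Inf),
               labels = PHENOTYPE_GROUPS, right = TRUE)
    if (!all(as.character(grp) == as.character(object@embryos$group)))
      msg <- c(msg, "group labels inconsistent with thresholds")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Cohort edit-fraction matrix (embryos x loci).
#' @param x A \code{Cohort}.
#' @export
editFractions <- function(x) x@fractions

#' @describeIn Cohort ordered phenotype groups.
#' @export
cohortGroups <- function(x) x@embryos$group

setMethod("show", "Cohort", function(object) {
  cat("Cohort: ", nrow(object@embryos), " embryos, loci ",
      paste(colnames(object@fractions), collapse = ", "),
      " (selection: ", object@selection, ")\n", sep = "")
  print(table(object@embryos$group))
})

#' Simulate a co-selection cohort
#'
#' @param params A \code{\link{cohortParams}} object.
#' @return A \code{\link{Cohort}}.
#' @examples
#' coh <- simulateCohort(cohortParams(nEmbryos = 50, seed = 7))
#' groupSummary(coh)
#' @export
simulateCohort <- function(params = cohortParams()) {
  if (!inherits(params, "CohortParams"))
    stop("params must come from cohortParams()", call. = FALSE)
  set.seed(params$seed)
  n <- params$nEmbryos
  loci <- params$loci
  nl <- nrow(loci)

  dose_sel <- stats::rbeta(n, params$doseAlpha, params$doseBeta)
  frac <- matrix(NA_real_, n, nl, dimnames = list(NULL, loci$locus))
  for (j in seq_len(nl)) {
    dose_j <- if (params$mode == "shared-dose") dose_sel
              else if (loci$locus[j] == params$selection) dose_sel
              else stats::rbeta(n, params$doseAlpha, params$doseBeta)
    p <- stats::plogis(loci$intercept[j] + loci$slope[j] * dose_j)
    if (is.finite(params$dispersion)) {
      p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      frac[, j] <- stats::rbeta(n, p * params$dispersion,
                                (1 - p) * params$dispersion)
    } else frac[, j] <- p
  }
  grp <- cut(frac[, params$selection], c(-Inf, params$thresholds, Inf),
             labels = PHENOTYPE_GROUPS, right = TRUE)
  grp <- factor(as.character(grp), levels = PHENOTYPE_GROUPS, ordered = TRUE)
  new("Cohort",
      embryos = data.frame(embryo_id = sprintf("emb%04d", seq_len(n)),
                           dose = dose_sel, group = grp,
                           stringsAsFactors = FALSE),
      fractions = frac, selection = params$selection,
      thresholds = params$thresholds)
}

#' Per-group mean edit percentages
#'
#' Means of the edit fraction per ordinal phenotype group (plus an overall
#' row), per locus. Empty groups are absent from the output, not reported
#' as zero.
#'
#' @param x A \code{\link{Cohort}}, or a long-format data.frame with
#'   columns \code{group}, \code{locus}, \code{edit_fraction}.
#' @return data.frame with columns \code{group}, \code{locus}, \code{n},
#'   \code{mean_pct}.
#' @export
groupSummary <- function(x) {
  long <- if (is(x, "Cohort")) as.data.frame(x) else as.data.frame(x)
  need <- c("group", "locus", "edit_fraction")
  if (!all(need %in% names(long)))
    stop("need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!nrow(long)) stop("empty cohort", call. = FALSE)
  long$group <- factor(as.character(long$group),
                       levels = c(PHENOTYPE_GROUPS, "overall"))
  parts <- lapply(split(long, long[, c("group", "locus")], drop = TRUE),
                  function(d) data.frame(
                    group = as.character(d$group[1]), locus = d$locus[1],
                    n = nrow(d), mean_pct = 100 * mean(d$edit_fraction),
                    stringsAsFactors = FALSE))
  res <- do.call(rbind, c(parts, make.row.names = FALSE))
  overall <- do.call(rbind, lapply(split(long, long$locus), function(d)
    data.frame(group = "overall", locus = d$locus[1], n = nrow(d),
               mean_pct = 100 * mean(d$edit_fraction),
               stringsAsFactors = FALSE)))
  res <- rbind(res, overall)
  res$group <- factor(res$group, levels = c(PHENOTYPE_GROUPS, "overall"))
  res <- res[order(res$locus, res$group), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @export
setMethod("as.data.frame", "Cohort",
  function(x, row.names = NULL, optional = FALSE, ...) {
    f <- x@fractions
    long <- do.call(rbind, lapply(colnames(f), function(l)
      data.frame(embryo_id = x@embryos$embryo_id,
                 group = as.character(x@embryos$group), locus = l,
                 edit_fraction = f[, l], stringsAsFactors = FALSE)))
    rownames(long) <- NULL
    long
  })

#' Permutation trend test for co-selection enrichment
#'
#' Tests whether embryos in more severely depigmented groups carry higher
#' edit fractions at a cargo locus. The statistic is the Spearman rank
#' correlation between the ordinal group and the cargo fraction (average
#' ranks for ties); the p-value permutes cargo fractions across embryos:
#' Monte Carlo \code{p = (1 + #{|stat*| >= |stat|}) / (1 + n_perm)}, or, for
#' \code{exact = TRUE} (n <= 9), full enumeration over all n! label
#' permutations, \code{p = #{|stat*| >= |stat|} / n!} (the identity
#' permutation guarantees p > 0).
#'
#' @param cohort A \code{\link{Cohort}}.
#' @param cargo_locus Column of \code{editFractions(cohort)} to test.
#' @param n_perm Number of Monte Carlo permutations.
#' @param seed Seed for the permutation draw.
#' @param exact Enumerate all permutations instead (n <= 9).
#' @return List (class \code{TrendResult}): \code{statistic},
#'   \code{p_value}, \code{n_perm}, \code{exact}, \code{seed}.
#' @export
trendTest <- function(cohort, cargo_locus, n_perm = 999L, seed = 1L,
                      exact = FALSE) {
  g <- as.integer(cohortGroups(cohort))
  y <- editFractions(cohort)[, cargo_locus]
  if (length(unique(g)) < 2L)
    stop("need >= 2 occupied groups", call. = FALSE)
  if (length(unique(y)) < 2L && length(unique(g)) < 2L)
    stop("statistic undefined: all observations tied", call. = FALSE)
  if (stats::sd(g) == 0 || stats::sd(y) == 0)
    stop("statistic undefined: all observations tied", call. = FALSE)
  rg <- rank(g); ry <- rank(y)
  rgc <- rg - mean(rg); ryc <- ry - mean(ry)
  denom <- sqrt(sum(rgc^2) * sum(ryc^2))
  obs <- sum(rgc * ryc) / denom
  n <- length(g)
  tol <- 1e-8

  if (exact) {
    if (n > 9L) stop("exact enumeration limited to n <= 9", call. = FALSE)
    perms <- .all_perms(n)
    stats_all <- as.vector((matrix(ryc[perms], nrow = nrow(perms)) %*%
                              rgc) / denom)
    p <- mean(abs(stats_all) >= abs(obs) - tol)
    res <- list(statistic = obs, p_value = p, n_perm = nrow(perms),
                exact = TRUE, seed = NA_integer_)
  } else {
    n_perm <- .assert_scalar_int(n_perm, "n_perm", 1L)
    set.seed(seed)
    perm <- replicate(n_perm, sample.int(n))
    stats_all <- as.vector(crossprod(matrix(ryc[perm], nrow = n), rgc)) /
      denom
    b <- sum(abs(stats_all) >= abs(obs) - tol)
    p <- (1 + b) / (1 + n_perm)
    res <- list(statistic = obs, p_value = p, n_perm = n_perm,
                exact = FALSE, seed = as.integer(seed))
  }
  structure(res, class = "TrendResult")
}

#' @export
print.TrendResult <- function(x, ...) {
  cat(sprintf(
    "Permutation trend test: Spearman rho = %.4f, p = %.4g (%s, %d perms)\n",
    x$statistic, x$p_value, if (x$exact) "exact" else "Monte Carlo",
    x$n_perm))
  invisible(x)
}

# all permutations of 1..n as a (n!) x n matrix, deterministic order
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Germline transmission proportion with exact confidence interval
#'
#' Proportion of edited offspring with a Clopper-Pearson exact 95\% CI,
#' for small founder-cross counts.
#'
#' @param k Number of edited (e.g. albino) offspring.
#' @param n Total offspring screened.
#' @return List (class \code{germlineProportion}): \code{percent} (one
#'   decimal), \code{lower}, \code{upper} (percent), \code{k}, \code{n}.
#' @examples
#' germlineProportion(28, 54)  # 51.9%
#' @export
germlineProportion <- function(k, n) {
  k <- .assert_scalar_int(k, "k", 0L)
  n <- .assert_scalar_int(n, "n", 1L)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  ci <- 100 * as.numeric(stats::binom.test(k, n)$conf.int)
  structure(list(percent = round(100 * k / n, 1),
                 lower = ci[1], upper = ci[2], k = k, n = n),
            class = "germlineProportion")
}

#' @export
print.germlineProportion <- function(x, ...) {
  cat(sprintf("%.1f%% (%d/%d; 95%% CI %.1f-%.1f%%)\n",
              x$percent, x$k, x$n, x$lower, x$upper))
  invisible(x)
}

#' Cohort TSV round trip
#'
#' Long format: \code{embryo_id}, \code{group}, \code{locus},
#' \code{edit_fraction}.
#'
#' @param cohort A \code{\link{Cohort}}.
#' @param path TSV path.
#' @param selection,thresholds Used by \code{readCohortTsv} to rebuild the
#'   object.
#' @export
writeCohortTsv <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortTsv
#' @export
readCohortTsv <- function(path, selection, thresholds = c(0.25, 0.6, 0.9)) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  wide <- split(long, long$locus)
  ids <- unique(long$embryo_id)
  frac <- vapply(wide, function(d)
    d$edit_fraction[match(ids, d$embryo_id)], numeric(length(ids)))
  grp <- cut(frac[, selection], c(-Inf, thresholds, Inf),
             labels = PHENOTYPE_GROUPS, right = TRUE)
  grp <- factor(as.character(grp), levels = PHENOTYPE_GROUPS, ordered = TRUE)
  new("Cohort",
      embryos = data.frame(embryo_id = ids, dose = NA_real_, group = grp,
                           stringsAsFactors = FALSE),
      fractions = frac, selection = selection, thresholds = thresholds)
}
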