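#' Label twin calls as concordant or discordant
#'
#' Marks each twin call with whether it passes the Mendelian filter
#' (matched in the co-twin and in at least one parent), per source and
#' family. Parent calls are not labelled — concordance is defined for the
#' twins' calls only.
#'
#' @param calls A call tibble covering all pedigree members.
#' @param pedigree A quartet pedigree tibble.
#' @param threshold RO threshold in `(0, 1]`.
#' @return The twins' rows of `calls` with a logical `concordant` column.
#' @export
label_concordance <- function(calls, pedigree, threshold = 0.7) {
  calls <- check_calls(calls)
  pedigree <- check_pedigree(pedigree)
  check_threshold(threshold)
  by_source <- split(calls, factor(calls$source, exclude = NULL))
  purrr::map_dfr(by_source, function(cs) {
    purrr::map_dfr(seq_len(nrow(pedigree)), function(i) {
      q <- pedigree[i, , drop = FALSE]
      parents <- cs[cs$sample_id %in% c(q$parent1, q$parent2), , drop = FALSE]
      purrr::map_dfr(list(c(q$twin1, q$twin2), c(q$twin2, q$twin1)), function(tw) {
        t_self <- cs[cs$sample_id == tw[1], , drop = FALSE]
        t_co <- cs[cs$sample_id == tw[2], , drop = FALSE]
        t_self$concordant <- best_min_ro(t_self, t_co) >= threshold &
          best_min_ro(t_self, parents) >= threshold
        t_self
      })
    })
  })
}

#' Annotate calls with sequence features
#'
#' Adds the covariates used in concordance-association analysis: call size,
#' GC content of the spanned reference sequence, distance to the nearer
#' chromosome end (a telomere proxy), and distance to the centromere
#' (0 when the call overlaps it).
#'
#' GC content is `(G + C) / (A + C + G + T)` over the call's span;
#' ambiguous bases are excluded from the denominator. When the context has
#' no sequence for a chromosome, `gc` is `NA` and a warning is raised.
#'
#' @param calls A call tibble (any extra columns, e.g. `concordant`, are
#'   preserved).
#' @param context A [genome_context()] with `chrom_lengths`, and ideally
#'   `centromere` and `sequence`.
#' @return `calls` with columns `size_bp`, `gc`, `dist_telomere`,
#'   `dist_centromere` appended.
#' @export
annotate_features <- function(calls, context) {
  calls <- check_calls(calls)
  if (!inherits(context, "genome_context")) {
    abort("`context` must be a genome_context object.")
  }
  lens <- context$chrom_lengths
  missing_chrom <- setdiff(unique(calls$chrom), names(lens))
  if (length(missing_chrom) > 0) {
    abort(sprintf("no chromosome length for \"%s\".", missing_chrom[1]))
  }
  if (nrow(calls) > 0 && any(calls$end > lens[calls$chrom] | calls$start < 0)) {
    abort("calls extend beyond chromosome bounds.")
  }
  calls$size_bp <- calls$end - calls$start
  calls$dist_telomere <- pmin(calls$start, lens[calls$chrom] - calls$end)

  calls$dist_centromere <- NA_real_
  if (!is.null(context$centromere)) {
    cen <- context$centromere
    idx <- match(calls$chrom, cen$chrom)
    cs <- cen$start[idx]; ce <- cen$end[idx]
    gap <- pmax(cs - calls$end, calls$start - ce, 0)
    calls$dist_centromere <- gap
  }

  calls$gc <- NA_real_
  if (!is.null(context$sequence)) {
    seqs <- context$sequence
    have <- calls$chrom %in% names(seqs)
    if (any(!have)) {
      warn(sprintf("no sequence for chromosome \"%s\"; gc set to NA.",
                   unique(calls$chrom[!have])[1]))
    }
    calls$gc[have] <- purrr::map2_dbl(
      calls$chrom[have],
      seq_len(nrow(calls))[have],
      function(chr, i) {
        span <- toupper(substr(seqs[[chr]], calls$start[i] + 1, calls$end[i]))
        bases <- strsplit(span, "", fixed = TRUE)[[1]]
        acgt <- sum(bases %in% c("A", "C", "G", "T"))
        if (acgt == 0) return(NA_real_)
        sum(bases %in% c("G", "C")) / acgt
      }
    )
  }
  calls
}

#' Feature-concordance association (multivariate logistic regression)
#'
#' Fits `concordant ~ size_bp + gc + dist_telomere + dist_centromere` by
#' maximum likelihood (iteratively reweighted least squares, convergence
#' tolerance 1e-8, at most 100 iterations) and reports Wald z-tests per
#' coefficient. Significance is assessed at the Bonferroni-corrected level
#' `alpha / n_features`; with the default four features and overall alpha
#' 0.01 the per-test threshold is 0.0025.
#'
#' Features are standardized internally for numerical stability by default;
#' estimates and standard errors are reported back on the original scale,
#' and Wald p-values are unaffected by the scaling.
#'
#' @param rows A feature table from [annotate_features()] with a logical
#'   `concordant` column.
#' @param alpha Overall significance level before Bonferroni correction.
#' @param standardize Standardize features before fitting (numerical
#'   stability only; results are reported on the original scale).
#' @param features Character vector of feature columns to include;
#'   features that are entirely `NA` are dropped with a warning.
#' @return An object of class `cnv_assoc` with [tidy()] and [glance()]
#'   methods: coefficient table (`term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `significant`), corrected alpha, convergence
#'   and separation flags.
#' @export
concordance_association <- function(rows, alpha = 0.01, standardize = TRUE,
                                    features = c("size_bp", "gc",
                                                 "dist_telomere",
                                                 "dist_centromere")) {
  if (!"concordant" %in% names(rows)) {
    abort("`rows` must contain a logical `concordant` column.")
  }
  if (length(unique(rows$concordant)) < 2) {
    abort("`concordant` must contain both outcome classes.")
  }
  keep <- features[vapply(features, function(f) {
    f %in% names(rows) && any(!is.na(rows[[f]]))
  }, logical(1))]
  dropped <- setdiff(features, keep)
  if (length(dropped) > 0) {
    warn(sprintf("dropping unavailable feature(s): %s.",
                 paste(dropped, collapse = ", ")))
  }
  if (length(keep) == 0) abort("no usable features.")
  df <- rows[stats::complete.cases(rows[, c("concordant", keep)]),
             c("concordant", keep)]
  if (nrow(df) <= length(keep)) abort("need more rows than features.")
  n_features <- length(keep)
  alpha_corrected <- alpha / n_features

  X <- as.matrix(df[, keep])
  qrX <- qr(cbind(`(Intercept)` = 1, X))
  if (qrX$rank < ncol(X) + 1) {
    bad <- qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)]
    dropped_cols <- c("(Intercept)", keep)[bad]
    abort(sprintf("singular design: feature(s) %s are collinear.",
                  paste(dropped_cols, collapse = ", ")))
  }

  centers <- rep(0, n_features)
  scales <- rep(1, n_features)
  if (standardize) {
    centers <- colMeans(X)
    scales <- apply(X, 2, sd)
    scales[scales == 0] <- 1
    X <- sweep(sweep(X, 2, centers), 2, scales, "/")
  }
  fit_df <- data.frame(.y = as.integer(df$concordant), X)
  names(fit_df) <- c(".y", keep)

  separation <- FALSE
  fit <- withCallingHandlers(
    glm(stats::reformulate(keep, ".y"), family = binomial(), data = fit_df,
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  converged <- fit$converged && !separation

  b <- coef(fit)
  V <- vcov(fit)
  # back-transform to the original feature scale
  est <- c(b[1] - sum(b[-1] * centers / scales), b[-1] / scales)
  grad0 <- c(1, -centers / scales)
  se <- c(sqrt(drop(t(grad0) %*% V %*% grad0)),
          sqrt(diag(V)[-1]) / scales)
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  table <- tibble::tibble(
    term = c("(Intercept)", keep),
    estimate = unname(est), std.error = unname(se),
    statistic = unname(z), p.value = unname(p),
    significant = c("(Intercept)", keep) != "(Intercept)" &
      unname(p) < alpha_corrected
  )
  structure(
    list(table = table, fit = fit, n = nrow(df), alpha = alpha,
         n_features = n_features, alpha_corrected = alpha_corrected,
         converged = converged, separation = separation),
    class = "cnv_assoc"
  )
}

#' @method tidy cnv_assoc
#' @export
tidy.cnv_assoc <- function(x, ...) x$table

#' @method glance cnv_assoc
#' @export
glance.cnv_assoc <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_features = x$n_features, alpha = x$alpha,
    alpha_corrected = x$alpha_corrected,
    converged = x$converged, separation = x$separation
  )
}

#' @export
print.cnv_assoc <- function(x, ...) {
  cat(sprintf(
    "Feature-concordance logistic regression (n = %d, alpha = %g, corrected = %g)\n",
    x$n, x$alpha, x$alpha_corrected
  ))
  if (!x$converged) cat("WARNING: fit did not converge cleanly",
                        if (x$separation) "(separation detected)", "\n")
  print(x$table)
  invisible(x)
}
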