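# Effect summaries from potential-outcome matrices.

#' Pairwise individualized treatment effects
#'
#' The per-subject effect of arm `j` relative to arm `k`:
#' `xi_jk(i) = Y[i, j] - Y[i, k]`.
#'
#' @param Y n x K potential-outcome matrix (or [po_matrix()]).
#' @param j,k arm indices (1-based), `j != k`.
#' @return length-n numeric vector.
#' @examples
#' pairwise_ite(rbind(c(1, 0)), 1, 2)  # 1
#' @export
pairwise_ite <- function(Y, j, k) {
  if (inherits(Y, "po_matrix")) Y <- Y$values
  Y <- as.matrix(Y)
  if (j == k) stop("pairwise_ite: j and k must differ")
  if (j < 1 || k < 1 || j > ncol(Y) || k > ncol(Y))
    stop("pairwise_ite: arm index out of range")
  Y[, j] - Y[, k]
}

#' Effect summary for one arm pair
#'
#' Computes the ITE vector for arms `(j, k)` plus the average effect over all
#' subjects (ATE), over subjects factually assigned to `j` (ATT) and over
#' subjects factually assigned to `k` (ATC).  For binary outcomes the
#' ITE takes values in `{-1, 0, 1}` and a sign-count table is attached, so
#' that `ate = (#{+1} - #{-1}) / n` exactly.  An empty treated or control
#' stratum yields an `NA` summary flagged in `$undefined` rather than a
#' propagated `NaN`.
#'
#' @param Y n x K outcome matrix (thresholded 0/1 entries for binary
#'   outcomes).
#' @param frame the [treatment_frame()] (supplies assignments).
#' @param j,k arm pair, 1-based.
#' @param subset optional row indices to summarize (e.g. an evaluation
#'   subset).
#' @return An object of class `effect_report` with `ite`, `ate`, `att`,
#'   `atc`, `counts`, `arm_pair`, `undefined`.
#' @export
effect_summary <- function(Y, frame, j = 1, k = 2, subset = NULL) {
  if (inherits(Y, "po_matrix")) Y <- Y$values
  ite <- pairwise_ite(Y, j, k)
  eta <- frame$eta
  if (!is.null(subset)) {
    ite <- ite[subset]
    eta <- eta[subset]
  }
  undefined <- character()
  att <- if (any(eta == j)) mean(ite[eta == j]) else {
    undefined <- c(undefined, "att"); NA_real_
  }
  atc <- if (any(eta == k)) mean(ite[eta == k]) else {
    undefined <- c(undefined, "atc"); NA_real_
  }
  binary <- frame$outcome_type == "binary"
  counts <- if (binary) {
    c(`-1` = sum(ite == -1), `0` = sum(ite == 0), `1` = sum(ite == 1))
  } else {
    table(cut(ite, breaks = pretty(ite, 20)))
  }
  structure(list(ite = ite, ate = mean(ite), att = att, atc = atc,
                 counts = counts, arm_pair = c(j, k), undefined = undefined),
            class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  cat(sprintf("<effect_report> arms %d vs %d: ATE %.4f, ATT %s, ATC %s\n",
              x$arm_pair[1], x$arm_pair[2], x$ate,
              formatC(x$att, format = "f", digits = 4),
              formatC(x$atc, format = "f", digits = 4)))
  if (length(x$counts) == 3) {
    cat("ITE counts  -1 /  0 / +1:", paste(x$counts, collapse = " / "), "\n")
  }
  if (length(x$undefined))
    cat("undefined strata:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Effect reports for several arm pairs
#'
#' One [effect_summary()] per pair, plus an additivity diagnostic for each
#' ordered triple of arms appearing among the pairs:
#' `ATE(j,l) - ATE(k,l) - ATE(j,k)`, which is identically zero when all
#' effects come from the same outcome matrix.
#'
#' @param Y n x K outcome matrix.
#' @param frame the [treatment_frame()].
#' @param pairs list of length-2 integer vectors.
#' @param subset optional row indices.
#' @return list with `reports` (named `"j_vs_k"`) and `additivity` (data
#'   frame, possibly empty).
#' @export
multi_treatment_report <- function(Y, frame, pairs, subset = NULL) {
  reports <- lapply(pairs, function(p) effect_summary(Y, frame, p[1], p[2],
                                                      subset = subset))
  names(reports) <- vapply(pairs, function(p) paste0(p[1], "_vs_", p[2]), "")
  ate <- function(j, k) {
    key <- paste0(j, "_vs_", k)
    if (key %in% names(reports)) return(reports[[key]]$ate)
    key2 <- paste0(k, "_vs_", j)
    if (key2 %in% names(reports)) return(-reports[[key2]]$ate)
    NA_real_
  }
  arms <- sort(unique(unlist(pairs)))
  adds <- list()
  if (length(arms) >= 3) {
    combs <- utils::combn(arms, 3)
    for (c_i in seq_len(ncol(combs))) {
      jkl <- combs[, c_i]
      j <- jkl[1]; k <- jkl[2]; l <- jkl[3]
      d <- ate(j, l) - ate(k, l) - ate(j, k)
      adds[[length(adds) + 1]] <- data.frame(j = j, k = k, l = l,
                                             diagnostic = d)
    }
  }
  list(reports = reports,
       additivity = if (length(adds)) do.call(rbind, adds) else
         data.frame(j = integer(), k = integer(), l = integer(),
                    diagnostic = numeric()))
}

#' Export an effect report
#'
#' Writes the summary (JSON) and the ITE vector with the sign-count table
#' (CSV).
#'
#' @param report an `effect_report`.
#' @param path_json,path_csv output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_effect_report <- function(report, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(list(arm_pair = report$arm_pair, ate = report$ate,
                              att = report$att, atc = report$atc,
                              counts = as.list(report$counts),
                              undefined = report$undefined),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(path_csv))
    write.csv(data.frame(ite = report$ite), path_csv, row.names = FALSE)
  invisible(c(path_json, path_csv))
}
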