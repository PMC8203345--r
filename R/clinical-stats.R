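#' Per-subject mean GFC z values over clusters
#'
#' For each cluster, averages the subject's Fisher-z GFC over the
#' cluster's member voxels — the single number per region that feeds the
#' clinical correlations and the classifier.
#'
#' @param gfce a [GFCExperiment-class].
#' @param clusters data.frame from [extractClusters()] (needs
#'   `cluster_id` and the `members` list-column).
#' @return data.frame with `id` plus one column per cluster, rows aligned
#'   to the experiment's subjects.
#' @export
extractClusterMeans <- function(gfce, clusters) {
  if (!nrow(clusters)) stop("no clusters to extract means from")
  mask <- S4Vectors::metadata(gfce)$mask
  Y <- SummarizedExperiment::assay(gfce, "gfc")
  lin <- maskLinearIndices(mask)
  out <- data.frame(id = colnames(Y))
  for (i in seq_len(nrow(clusters))) {
    mem <- clusters$members[[i]]
    if (is.null(mem) || !nrow(mem)) stop("empty cluster: ",
                                         clusters$cluster_id[i])
    g <- mask@gridShape
    memLin <- (mem[, 3L] - 1L) * (g[1L] * g[2L]) +
              (mem[, 2L] - 1L) * g[1L] + mem[, 1L]
    rows <- match(memLin, lin)
    if (anyNA(rows)) stop("cluster voxels outside the shared mask")
    out[[clusters$cluster_id[i]]] <- colMeans(Y[rows, , drop = FALSE])
  }
  out
}

#' Screen Pearson correlations between cluster GFC and clinical variables
#'
#' For every (cluster, variable) pair among the filtered group (default:
#' patients only, since clinical scales and lipid panels are collected
#' for patients), computes the Pearson r and two-sided p with pairwise
#' deletion of missing values. The Bonferroni threshold is
#' `alpha / n_tests`, where the test family is either all pairs actually
#' tested (`family = "all"`, default) or the variables within each
#' cluster (`family = "per_cluster"`). Both the uncorrected p and the
#' applied threshold are reported, so either multiplicity reading can be
#' reproduced from the output. Shapiro-Wilk normality of each cluster's
#' means is assessed and reported (not used as a gate).
#'
#' @param means cluster-mean table from [extractClusterMeans()].
#' @param subjects subject table with `id`, `group` and the clinical
#'   columns.
#' @param variables character vector of clinical column names.
#' @param group `"patient"`, `"control"` or `"all"`.
#' @param family `"all"` or `"per_cluster"`.
#' @param alpha family-wise level, default 0.05.
#' @return data.frame with one row per tested pair: `cluster`,
#'   `variable`, `n`, `r`, `p`, `p_threshold_bonferroni`, `significant`;
#'   Shapiro-Wilk p values per cluster are in
#'   `attr(, "shapiro_p")`. Pairs with fewer than 3 complete
#'   observations are skipped with a warning.
#' @export
correlateClinical <- function(means, subjects, variables,
                              group = c("patient", "control", "all"),
                              family = c("all", "per_cluster"),
                              alpha = 0.05) {
  group <- match.arg(group)
  family <- match.arg(family)
  missingVars <- setdiff(variables, names(subjects))
  if (length(missingVars))
    stop("variable(s) absent from subject table: ",
         paste(missingVars, collapse = ", "))
  tab <- merge(means, subjects, by = "id", sort = FALSE)
  if (group != "all") tab <- tab[tab$group == group, , drop = FALSE]
  clusterCols <- setdiff(names(means), "id")

  shapiro <- vapply(clusterCols, function(cl) {
    v <- tab[[cl]][is.finite(tab[[cl]])]
    if (length(unique(v)) < 3L) NA_real_ else shapiro.test(v)$p.value
  }, numeric(1))

  rows <- list()
  for (cl in clusterCols) {
    for (v in variables) {
      ok <- complete.cases(tab[[cl]], tab[[v]])
      n <- sum(ok)
      if (n < 3L) {
        warning(sprintf("skipping %s ~ %s: only %d complete pair(s)",
                        cl, v, n))
        next
      }
      ct <- cor.test(tab[[cl]][ok], tab[[v]][ok], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, variable = v, n = n,
        r = unname(ct$estimate), p = ct$p.value)
    }
  }
  if (!length(rows)) {
    res <- data.frame(cluster = character(), variable = character(),
                      n = integer(), r = numeric(), p = numeric(),
                      p_threshold_bonferroni = numeric(),
                      significant = logical())
    attr(res, "shapiro_p") <- shapiro
    return(res)
  }
  res <- do.call(rbind, rows)
  if (family == "all") {
    res$p_threshold_bonferroni <- alpha / nrow(res)
  } else {
    nt <- table(res$cluster)
    res$p_threshold_bonferroni <- alpha / as.numeric(nt[res$cluster])
  }
  res$significant <- res$p < res$p_threshold_bonferroni
  attr(res, "shapiro_p") <- shapiro
  res
}
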