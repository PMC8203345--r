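#' Dice overlap between two voxel sets
#'
#' `2|A∩B| / (|A| + |B|)` on voxel coordinate sets — the overlap score
#' used to judge recovery of a planted hub by an extracted cluster.
#'
#' @param a,b integer matrices (voxels x 3) of voxel coordinates.
#' @param gridShape integer(3) grid the coordinates live on.
#' @return Dice coefficient in `[0, 1]`.
#' @export
diceOverlap <- function(a, b, gridShape) {
  linOf <- function(co)
    (co[, 3L] - 1L) * (gridShape[1L] * gridShape[2L]) +
    (co[, 2L] - 1L) * gridShape[1L] + co[, 1L]
  la <- unique(linOf(a)); lb <- unique(linOf(b))
  2 * length(intersect(la, lb)) / (length(la) + length(lb))
}

#' Run the full GFC study on an in-memory cohort
#'
#' Sequences the whole analysis: frame-wise-displacement QC with subject
#' exclusion, gray-matter mask construction, per-subject GFC maps
#' (volumes are streamed one subject at a time), voxel-wise
#' covariate-adjusted group GLM, family-wise-error correction, cluster
#' extraction, cluster-mean clinical correlation screening, and
#' single-region LOOCV SVM classification of every significant cluster.
#'
#' @param cohort a `"gfc_cohort"` from [generateCohort()], or any list
#'   with the same fields assembled from files.
#' @param gmThreshold gray-matter probability cutoff (strict >).
#' @param zOrder GFC z-transform order, see [computeGFC()].
#' @param meanFdLimit,maxAbsTranslation,maxAbsRotationDeg motion QC
#'   limits, see [applyExclusion()].
#' @param covariates nuisance covariates for the design.
#' @param fweMethod,alpha,nPermutations FWE settings, see [fweCorrect()].
#' @param corrVariables clinical variables to screen (default: the
#'   cohort's planted-effect variables when present).
#' @param corrFamily Bonferroni family definition, see
#'   [correlateClinical()].
#' @param classify run the per-cluster LOOCV SVM (default `TRUE`).
#' @param nestedSvm nested hyperparameter tuning, see [loocvSvm()].
#' @param seed global seed; per-stage seeds are derived from it
#'   deterministically.
#' @return list with `qc`, `mask`, `gfce` ([GFCExperiment-class]),
#'   `design`, `stat`, `fwe`, `clusters`, `clusterMeans`,
#'   `correlations`, `classifiers` (list per cluster), and `seed`.
#' @export
runStudy <- function(cohort, gmThreshold = 0.2,
                     zOrder = "z_of_mean_r",
                     meanFdLimit = 0.2, maxAbsTranslation = 2,
                     maxAbsRotationDeg = 2,
                     covariates = c("age", "sex", "education", "mean_fd"),
                     fweMethod = "permutation_maxT", alpha = 0.05,
                     nPermutations = 1000L,
                     corrVariables = NULL, corrFamily = "all",
                     classify = TRUE, nestedSvm = TRUE, seed = 1L) {
  fds <- lapply(cohort$motion, computeFD)
  qc <- applyExclusion(fds, cohort$motion, meanFdLimit = meanFdLimit,
                       maxAbsTranslation = maxAbsTranslation,
                       maxAbsRotationDeg = maxAbsRotationDeg)
  meanFdTab <- vapply(fds, function(f) f@meanFD, numeric(1))
  names(meanFdTab) <- vapply(fds, function(f) f@subjectId, character(1))

  subjects <- cohort$subjects
  subjects$mean_fd <- unname(meanFdTab[subjects$id])
  kept <- subjects$id %in% qc$kept
  subjectsKept <- subjects[kept, , drop = FALSE]

  mask <- buildGrayMask(cohort$gmProb, gmThreshold, affine = cohort$affine)
  keptIdx <- which(kept)
  maps <- vector("list", length(keptIdx))
  for (j in seq_along(keptIdx)) {
    i <- keptIdx[j]
    vs <- if (!is.null(cohort$volumes)) cohort$volumes[[i]]
          else cohortVolume(cohort, i)
    maps[[j]] <- computeGFC(vs, mask, zOrder = zOrder)
  }
  gfce <- gfcExperiment(maps, subjectsKept)

  design <- designMatrix(subjectsKept, covariates = covariates)
  stat <- fitVoxelwiseGLM(gfce, design)
  fwe <- fweCorrect(stat, gfce, design, method = fweMethod, alpha = alpha,
                    nPermutations = nPermutations,
                    seed = stageSeed(seed, "fwe"))
  clusters <- extractClusters(stat, fwe)

  clusterMeans <- NULL; correlations <- NULL; classifiers <- list()
  if (nrow(clusters)) {
    clusterMeans <- extractClusterMeans(gfce, clusters)
    if (is.null(corrVariables) && !is.null(cohort$truth))
      corrVariables <- names(cohort$truth$plantedR)
    if (!is.null(corrVariables) && length(corrVariables))
      correlations <- correlateClinical(clusterMeans, subjectsKept,
                                        corrVariables, group = "patient",
                                        family = corrFamily)
    if (classify) {
      for (cl in clusters$cluster_id) {
        classifiers[[cl]] <- loocvSvm(
          clusterMeans[[cl]], subjectsKept$group, nested = nestedSvm,
          region = cl, seed = stageSeed(seed, paste0("svm-", cl)))
      }
    }
  }
  list(qc = qc, mask = mask, gfce = gfce, design = design, stat = stat,
       fwe = fwe, clusters = clusters, clusterMeans = clusterMeans,
       correlations = correlations, classifiers = classifiers,
       seed = seed)
}

readCohortFromDir <- function(paths, tr = NULL) {
  gm <- readProbabilityMap(paths$gm_prob)
  subjects <- read.table(paths$subjects, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  boldFiles <- file.path(paths$bold_dir,
                         paste0(subjects$id, "_bold.nii.gz"))
  motionFiles <- file.path(paths$motion_dir,
                           paste0("rp_", subjects$id, ".txt"))
  missing <- c(boldFiles[!file.exists(boldFiles)],
               motionFiles[!file.exists(motionFiles)])
  if (length(missing))
    stop("missing input file(s): ", paste(head(missing, 3), collapse = ", "))
  volumes <- lapply(seq_len(nrow(subjects)), function(i)
    readVolumeSeries(boldFiles[i], subjectId = subjects$id[i], tr = tr))
  motion <- lapply(seq_len(nrow(subjects)), function(i)
    readMotionTrace(motionFiles[i], subjectId = subjects$id[i]))
  structure(list(spec = NULL, volumes = volumes, gmProb = gm$prob,
                 affine = gm$affine, motion = motion, subjects = subjects,
                 truth = NULL), class = "gfc_cohort")
}

#' Run the pipeline from a config and persist every intermediate
#'
#' Drives [runStudy()] from a YAML file or config list and writes all
#' stage outputs under `outDir`: the QC report (`qc.tsv`), per-subject
#' GFC maps (NIfTI + JSON sidecars), the t and -log10(p) maps
#' (`tmap.nii.gz`, `logpmap.nii.gz`), the cluster table
#' (`clusters.tsv`), the FWE report (`fwe.json`), cluster means
#' (`cluster_means.tsv`), clinical correlations (`correlations.tsv`),
#' per-cluster classifier reports (`classifier_<cluster>.json`), and a
#' run manifest (`manifest.json`: config hash, seed, file md5 sums).
#' Reruns with an identical config and seed reproduce all outputs
#' bit-identically on one platform.
#'
#' Config keys (all optional except either `simulate` or `paths`):
#' `simulate` (arguments for [cohortSpec()]), `paths` (with `bold_dir`,
#' `gm_prob`, `motion_dir`, `subjects`), `gm_threshold`, `z_order`,
#' `qc` (`mean_fd_limit`, `max_abs_translation`, `max_abs_rotation_deg`),
#' `fwe` (`method`, `alpha`, `n_permutations`), `correlate`
#' (`variables`, `family`), `classify` (`enabled`, `nested`), `seed`.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param outDir output directory.
#' @param writeGfcMaps write the per-subject GFC NIfTI maps (default
#'   `TRUE`; they are the bulkiest intermediate).
#' @return the [runStudy()] result, invisibly, with `outDir` attached.
#' @export
runPipeline <- function(config, outDir = NULL, writeGfcMaps = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(outDir)) outDir <- config$out_dir
  if (is.null(outDir)) stop("an output directory is required")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  cohort <- if (!is.null(config$simulate)) {
    args <- config$simulate
    args$seed <- as.integer(args$seed %||% stageSeed(seed, "simulate"))
    if (!is.null(args$clinicalEffects))
      args$clinicalEffects <- unlist(args$clinicalEffects)
    generateCohort(do.call(cohortSpec, args), includeVolumes = FALSE)
  } else if (!is.null(config$paths)) {
    readCohortFromDir(config$paths, tr = config$tr)
  } else stop("config needs either a 'simulate' block or 'paths'")

  qcCfg <- config$qc %||% list()
  fweCfg <- config$fwe %||% list()
  corrCfg <- config$correlate %||% list()
  clsCfg <- config$classify %||% list()
  res <- runStudy(
    cohort,
    gmThreshold = config$gm_threshold %||% 0.2,
    zOrder = config$z_order %||% "z_of_mean_r",
    meanFdLimit = qcCfg$mean_fd_limit %||% 0.2,
    maxAbsTranslation = qcCfg$max_abs_translation %||% 2,
    maxAbsRotationDeg = qcCfg$max_abs_rotation_deg %||% 2,
    fweMethod = fweCfg$method %||% "permutation_maxT",
    alpha = fweCfg$alpha %||% 0.05,
    nPermutations = fweCfg$n_permutations %||% 1000L,
    corrVariables = if (!is.null(corrCfg$variables))
                      unlist(corrCfg$variables) else NULL,
    corrFamily = corrCfg$family %||% "all",
    classify = clsCfg$enabled %||% TRUE,
    nestedSvm = clsCfg$nested %||% TRUE,
    seed = seed)

  # --- persist ---
  write.table(res$qc$log, file.path(outDir, "qc.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (writeGfcMaps) {
    mapDir <- file.path(outDir, "gfc_maps")
    dir.create(mapDir, showWarnings = FALSE)
    Y <- SummarizedExperiment::assay(res$gfce, "gfc")
    for (id in colnames(Y)) {
      map <- new("GFCMap", values = Y[, id], subjectId = id,
                 zOrder = S4Vectors::metadata(res$gfce)$zOrder,
                 mask = res$mask)
      writeGFCMap(map, file.path(mapDir, paste0(id, "_gfc.nii.gz")))
    }
  }
  write3DNifti(maskToVolume(res$stat@t, res$mask), res$mask@affine,
               file.path(outDir, "tmap.nii.gz"))
  write3DNifti(maskToVolume(-log10(res$stat@p), res$mask),
               res$mask@affine, file.path(outDir, "logpmap.nii.gz"))
  clTab <- res$clusters[setdiff(names(res$clusters), "members")]
  write.table(clTab, file.path(outDir, "clusters.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(method = res$fwe@method, n_permutations = res$fwe@nPermutations,
         alpha = res$fwe@alpha, threshold = res$fwe@threshold,
         n_significant = sum(res$fwe@significant), seed = res$fwe@seed),
    file.path(outDir, "fwe.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$clusterMeans))
    write.table(res$clusterMeans, file.path(outDir, "cluster_means.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$correlations))
    write.table(res$correlations, file.path(outDir, "correlations.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  for (cl in names(res$classifiers)) {
    r <- res$classifiers[[cl]]
    jsonlite::write_json(
      list(region = r$region, kernel = r$kernel, nested = r$nested,
           tp = r$tp, fn = r$fn, tn = r$tn, fp = r$fp,
           sensitivity = r$sensitivity, specificity = r$specificity,
           accuracy = r$accuracy, warnings = r$warnings),
      file.path(outDir, paste0("classifier_", cl, ".json")),
      auto_unbox = TRUE, digits = NA)
  }

  cfgPath <- file.path(outDir, "config_used.yaml")
  yaml::write_yaml(config, cfgPath)
  outputs <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    seed = seed,
    config_md5 = unname(tools::md5sum(cfgPath)),
    files = as.list(setNames(unname(tools::md5sum(outputs)),
                             list.files(outDir, recursive = TRUE))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE)
  attr(res, "outDir") <- outDir
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
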