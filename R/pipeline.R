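#' @include synthetic.R
NULL

#' Study configuration
#'
#' Assembles (and validates) the configuration of a full analysis run.
#' Defaults encode the study protocol: 0.020 mm clearance in offset mode,
#' alpha = 0.05, and the published normalizing powers per endpoint
#' (RAV 0.125, dAV 0.225, EVL 0.25; \code{"auto"} selects by grid search).
#'
#' @param inputDir directory with \code{<tooth_id>_<T0|T1|T2>.stl} files.
#' @param groupTable CSV with columns \code{tooth_id}, \code{group}.
#' @param outputDir where reports are written.
#' @param clearance,clearanceMode,integrationStep see
#'   \code{\link{volumetryConfig}}.
#' @param powers named list of transform exponents (or \code{"auto"}) for
#'   endpoints RAV, dAV, EVL.
#' @param alpha significance level.
#' @param roiOverrides optional JSON file of per-tooth ROI overrides
#'   (array of \code{\{tooth_id, center_mm, frame, side_mm\}}).
#' @param seed integer seed (analysis is deterministic; kept for
#'   provenance).
#' @param file optional YAML or JSON configuration file; entries given in
#'   the call override file entries.
#' @return A named list (class \code{"studyConfig"}).
#' @export
studyConfig <- function(inputDir = NULL, groupTable = NULL,
                        outputDir = NULL, clearance = 0.020,
                        clearanceMode = "offset", integrationStep = 0.010,
                        powers = list(RAV = 0.125, dAV = 0.225,
                                      EVL = 0.25),
                        alpha = 0.05, roiOverrides = NULL, seed = 1L,
                        file = NULL) {
  cfg <- list(inputDir = inputDir, groupTable = groupTable,
              outputDir = outputDir, clearance = clearance,
              clearanceMode = clearanceMode,
              integrationStep = integrationStep, powers = powers,
              alpha = alpha, roiOverrides = roiOverrides, seed = seed)
  if (!is.null(file)) {
    stored <- if (grepl("\\.json$", file, ignore.case = TRUE))
      jsonlite::fromJSON(file, simplifyVector = TRUE)
    else yaml::read_yaml(file)
    given <- !vapply(cfg, is.null, TRUE) &
      names(cfg) %in% names(as.list(match.call()))
    cfg <- utils::modifyList(utils::modifyList(cfg, stored),
                             cfg[given])
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("usage error in key 'alpha': must be in (0, 1)")
  if (!is.numeric(cfg$clearance) || cfg$clearance < 0)
    stop("usage error in key 'clearance': must be >= 0")
  class(cfg) <- "studyConfig"
  cfg
}

# analysis of one loaded triplet: register, place ROI, measure
.processTriplet <- function(triplet, vcfg, roiOverride = NULL,
                            mask = NULL) {
  aligned <- alignTriplet(triplet, mask = mask,
                          clearance = max(vcfg@clearance, 0.02))
  dev <- signedDeviation(aligned@t1, aligned@t0)
  roi <- placeROI(dev, clearance = max(vcfg@clearance, 0.02),
                  override = roiOverride)
  rep <- computeVolumeReport(aligned, roi, vcfg,
                             alignmentRMS = attr(aligned, "rmsT1"))
  attr(rep, "roi") <- roi
  rep
}

.fmtNum <- function(df) {
  for (cl in names(df)) if (is.numeric(df[[cl]]))
    df[[cl]] <- ifelse(is.na(df[[cl]]), "NA", sprintf("%.9g", df[[cl]]))
  df
}

#' Volumetry stage: meshes to per-tooth volumes
#'
#' Loads every tooth listed in the group table, registers T1/T2 to T0,
#' places the 5 mm ROI automatically (or from an override file), and
#' computes the per-tooth volume report. Teeth failing any geometric stage
#' are skipped with a recorded reason; the run continues.
#'
#' @param config a \code{\link{studyConfig}}.
#' @return A list with \code{volumes} (data.frame of per-tooth rows) and
#'   \code{manifest} (per-tooth status). When \code{config$outputDir} is
#'   set, writes \code{volumes.csv} there.
#' @export
volumetryStage <- function(config) {
  groups <- utils::read.csv(config$groupTable,
                            colClasses = c(tooth_id = "character"))
  vcfg <- volumetryConfig(clearance = config$clearance,
                          clearanceMode = config$clearanceMode,
                          integrationStep = config$integrationStep)
  overrides <- list()
  if (!is.null(config$roiOverrides)) {
    arr <- jsonlite::fromJSON(config$roiOverrides,
                              simplifyVector = FALSE)
    for (o in arr)
      overrides[[o$tooth_id]] <- list(
        center = as.numeric(unlist(o$center_mm)),
        frame = if (!is.null(o$frame))
          matrix(as.numeric(unlist(o$frame)), 3, 3) else diag(3),
        side = o$side_mm %||% 5)
  }
  rows <- list()
  manifest <- list()
  for (k in seq_len(nrow(groups))) {
    id <- groups$tooth_id[k]
    paths <- file.path(config$inputDir,
                       paste0(id, "_T", 0:2, ".stl"))
    if (!all(file.exists(paths))) {
      msg <- paste("missing scan file(s):",
                   paste(basename(paths[!file.exists(paths)]),
                         collapse = ", "))
      warning("tooth '", id, "': ", msg)
      manifest[[id]] <- list(status = "error", reason = msg)
      next
    }
    res <- tryCatch({
      tri <- new("ScanTriplet", toothId = id,
                 group = as.integer(groups$group[k]),
                 t0 = readSTL(paths[1]), t1 = readSTL(paths[2]),
                 t2 = readSTL(paths[3]))
      .processTriplet(tri, vcfg, roiOverride = overrides[[id]])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("tooth '", id, "': ", conditionMessage(res))
      manifest[[id]] <- list(status = "error",
                             reason = conditionMessage(res))
    } else {
      manifest[[id]] <- list(status = "ok", reason = "")
      rows[[id]] <- res
    }
  }
  volumes <- do.call(rbind, rows)
  rownames(volumes) <- NULL
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(.fmtNum(volumes),
                     file.path(config$outputDir, "volumes.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(volumes = volumes, manifest = manifest)
}

#' Statistics stage: per-tooth volumes to group comparison tables
#'
#' Descriptive tables (per treatment and pooled) for AV, RAV, dAV and EVL,
#' and the transform-then-ANOVA/Tukey comparison for RAV, dAV and EVL at
#' the configured powers. Undefined dAV values are excluded. Requires at
#' least 2 groups with at least 3 usable teeth each.
#'
#' @param volumes per-tooth data.frame from \code{\link{volumetryStage}}
#'   (or its \code{volumes.csv}).
#' @param config a \code{\link{studyConfig}}.
#' @return A list with \code{descriptives} (data.frame),
#'   \code{anova} (data.frame, one row per endpoint), \code{tukey}
#'   (data.frame, one row per endpoint x pair), and \code{results} (the
#'   full \code{\link{analyzeEndpoint}} objects). Writes
#'   \code{descriptives.csv}, \code{anova.csv}, \code{tukey.csv} when
#'   \code{config$outputDir} is set.
#' @export
statsStage <- function(volumes, config = studyConfig()) {
  if (is.character(volumes))
    volumes <- utils::read.csv(volumes,
                               colClasses = c(tooth_id = "character"))
  endpointCols <- c(AV = "AV_mm3", RAV = "RAV_mm3", dAV = "dAV",
                    EVL = "EVL_mm3")
  glev <- sort(unique(volumes$group))
  usable <- vapply(glev, function(g) sum(volumes$group == g), 1L)
  if (sum(usable >= 3L) < 2L)
    stop("statistical-stage abort: fewer than 2 groups with >= 3 teeth")
  desc <- list()
  for (ep in names(endpointCols)) {
    vals <- volumes[[endpointCols[[ep]]]]
    desc[[paste0(ep, "_all")]] <-
      cbind(endpoint = ep, treatment = "all",
            descriptiveStats(vals))
    for (g in glev)
      desc[[paste0(ep, "_", g)]] <-
        cbind(endpoint = ep, treatment = as.character(g),
              descriptiveStats(vals[volumes$group == g]))
  }
  desc <- do.call(rbind, desc)
  rownames(desc) <- NULL
  results <- list()
  anova_rows <- list()
  tukey_rows <- list()
  for (ep in c("RAV", "dAV", "EVL")) {
    vals <- volumes[[endpointCols[[ep]]]]
    gr <- lapply(glev, function(g) {
      v <- vals[volumes$group == g]
      v[!is.na(v)]
    })
    names(gr) <- as.character(glev)
    pw <- config$powers[[ep]] %||% "auto"
    res <- analyzeEndpoint(gr, power = pw, alpha = config$alpha)
    results[[ep]] <- res
    anova_rows[[ep]] <- data.frame(
      endpoint = ep, power = res$power,
      shapiro_p_min = min(res$shapiroP),
      F = res$anova@F, df_between = res$anova@dfBetween,
      df_within = res$anova@dfWithin, p = res$anova@p)
    tk <- res$tukey@pairs
    tukey_rows[[ep]] <- cbind(endpoint = ep,
                              pair = paste0(tk$group2, "-", tk$group1),
                              tk[c("difference", "p_adj",
                                   "significant")])
  }
  anova <- do.call(rbind, anova_rows)
  tukey <- do.call(rbind, tukey_rows)
  rownames(anova) <- rownames(tukey) <- NULL
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(.fmtNum(desc),
                     file.path(config$outputDir, "descriptives.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(.fmtNum(anova),
                     file.path(config$outputDir, "anova.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(.fmtNum(tukey),
                     file.path(config$outputDir, "tukey.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(descriptives = desc, anova = anova, tukey = tukey,
       results = results)
}

#' Run the full study analysis
#'
#' End-to-end orchestration: load every listed tooth, register, measure
#' volumes inside the ROI, and run the group statistics. Outputs are
#' deterministic for a fixed configuration and seed; teeth failing a
#' geometric stage are excluded from statistics and listed in the
#' manifest.
#'
#' @param config a \code{\link{studyConfig}} with at least
#'   \code{inputDir}, \code{groupTable} and (for file output)
#'   \code{outputDir}.
#' @return A list with \code{volumes}, \code{descriptives}, \code{anova},
#'   \code{tukey}, \code{results} and \code{manifest}. When
#'   \code{outputDir} is set, writes \code{volumes.csv},
#'   \code{descriptives.csv}, \code{anova.csv}, \code{tukey.csv} and
#'   \code{manifest.json}.
#' @export
runStudy <- function(config) {
  vol <- volumetryStage(config)
  stats <- statsStage(vol$volumes, config)
  manifest <- list(
    config = config[setdiff(names(config), "powers")],
    powers = config$powers,
    software = paste("adhevol",
                     as.character(utils::packageVersion("adhevol"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    teeth = vol$manifest)
  if (!is.null(config$outputDir)) {
    jsonlite::write_json(manifest,
                         file.path(config$outputDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  c(vol["volumes"], stats, list(manifest = manifest))
}
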