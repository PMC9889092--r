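## Reading and writing EBSD text maps (CTF and ANG dialects), run
## configuration, and the two end-to-end drivers: map analysis and the
## phylogenetic comparative analysis.

#' Read an orientation map from an EBSD text file
#'
#' CTF dialect: a "Channel Text File" header carrying XCells/YCells and
#' XStep/YStep, then whitespace-separated columns including Phase, X, Y and
#' Euler1-3 (degrees, Bunge ZXZ); rows with Phase 0 are non-indexed. ANG
#' dialect: '#' header lines, then phi1, PHI, phi2 (radians), x, y, image
#' quality, confidence index, phase; rows with a negative confidence index
#' are non-indexed. Grid spacing is inferred from the coordinates and
#' checked for regularity.
#'
#' @param path file path.
#' @param dialect "ctf" or "ang".
#' @return an \linkS4class{OrientationMap}.
#' @export
readOrientationMap <- function(path, dialect = c("ctf", "ang")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (dialect == "ctf") .readCtf(path) else .readAng(path)
}

.gridFromCoords <- function(xy) {
  ux <- sort(unique(xy))
  if (length(ux) < 2L) return(list(step = 1, n = length(ux), origin = ux[1L]))
  d <- diff(ux)
  step <- stats::median(d)
  if (any(abs(d - step) > 1e-4 * step))
    stop("irregular grid: coordinate spacing is not constant")
  list(step = step, n = length(ux), origin = ux[1L])
}

.readCtf <- function(path) {
  lines <- readLines(path, n = 50L)
  if (!grepl("Channel Text File", lines[1L], fixed = TRUE))
    stop("not a CTF file (missing 'Channel Text File' header)")
  headerEnd <- grep("^Phase\\s", lines)[1L]
  if (is.na(headerEnd)) stop("malformed CTF: no column header row")
  cols <- strsplit(trimws(lines[headerEnd]), "\\s+")[[1L]]
  dat <- utils::read.table(path, skip = headerEnd, col.names = cols,
                           colClasses = "numeric")
  need <- c("Phase", "X", "Y", "Euler1", "Euler2", "Euler3")
  if (!all(need %in% cols)) stop("malformed CTF: missing columns ",
                                 paste(setdiff(need, cols), collapse = ", "))
  if (any(!is.finite(as.matrix(dat[need]))))
    stop("malformed numerics in CTF body")
  phases <- unique(dat$Phase)
  if (any(!phases %in% c(0, 1)))
    stop("unknown phase count: CTF phases other than {0, 1} are not supported")
  gx <- .gridFromCoords(dat$X); gy <- .gridFromCoords(dat$Y)
  if (abs(gx$step - gy$step) > 1e-6 * gx$step)
    stop("irregular grid: X and Y steps differ")
  W <- gx$n; H <- gy$n
  if (nrow(dat) != W * H) stop("irregular grid: row count != XCells * YCells")
  xi <- as.integer(round((dat$X - gx$origin) / gx$step)) + 1L
  yi <- as.integer(round((dat$Y - gy$origin) / gy$step)) + 1L
  ord <- order(xi, yi)              # column-major (y fastest)
  dat <- dat[ord, , drop = FALSE]
  q <- eulerToQuat(dat$Euler1, dat$Euler2, dat$Euler3)
  indexed <- matrix(dat$Phase != 0, H, W)
  OrientationMap(q, W, H, gx$step, indexed = indexed)
}

.readAng <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  dat <- utils::read.table(text = body, colClasses = "numeric")
  if (ncol(dat) < 8L) stop("malformed ANG: expected >= 8 columns")
  names(dat)[1:8] <- c("phi1", "PHI", "phi2", "x", "y", "iq", "ci", "phase")
  if (any(!is.finite(as.matrix(dat[, 1:8])))) stop("malformed numerics in ANG body")
  gx <- .gridFromCoords(dat$x); gy <- .gridFromCoords(dat$y)
  if (abs(gx$step - gy$step) > 1e-6 * gx$step)
    stop("irregular grid: x and y steps differ")
  W <- gx$n; H <- gy$n
  if (nrow(dat) != W * H) stop("irregular grid: row count mismatch")
  xi <- as.integer(round((dat$x - gx$origin) / gx$step)) + 1L
  yi <- as.integer(round((dat$y - gy$origin) / gy$step)) + 1L
  dat <- dat[order(xi, yi), , drop = FALSE]
  r2d <- 180 / pi
  q <- eulerToQuat(dat$phi1 * r2d, dat$PHI * r2d, dat$phi2 * r2d)
  indexed <- matrix(dat$ci >= 0, H, W)
  OrientationMap(q, W, H, gx$step, indexed = indexed)
}

#' Write an orientation map as an EBSD text file
#'
#' @param map an \linkS4class{OrientationMap}.
#' @param path output file.
#' @param dialect "ctf" (Euler angles in degrees) or "ang" (radians).
#' @return the path, invisibly.
#' @export
writeOrientationMap <- function(map, path, dialect = c("ctf", "ang")) {
  dialect <- match.arg(dialect)
  H <- mapHeight(map); W <- mapWidth(map); step <- mapStep(map)
  eul <- quatToEuler(mapQuats(map))
  xi <- rep(seq_len(W), each = H); yi <- rep(seq_len(H), W)
  indexed <- as.vector(mapIndexed(map))
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "ctf") {
    writeLines(c("Channel Text File",
                 "Prj synthetic eggshell map",
                 sprintf("XCells\t%d", W), sprintf("YCells\t%d", H),
                 sprintf("XStep\t%.6f", step), sprintf("YStep\t%.6f", step),
                 "Phases\t1",
                 "Phase\tX\tY\tBands\tError\tEuler1\tEuler2\tEuler3\tMAD\tBC\tBS"),
               con)
    df <- data.frame(Phase = as.integer(indexed), X = (xi - 1L) * step,
                     Y = (yi - 1L) * step, Bands = 8L, Error = 0L,
                     Euler1 = round(eul$phi1, 6), Euler2 = round(eul$Phi, 6),
                     Euler3 = round(eul$phi2, 6), MAD = 0.5, BC = 128L, BS = 128L)
    utils::write.table(df, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    writeLines(c("# HEADER: synthetic eggshell map",
                 sprintf("# GRID: SqrGrid"),
                 sprintf("# XSTEP: %.6f", step), sprintf("# YSTEP: %.6f", step)),
               con)
    d2r <- pi / 180
    df <- data.frame(phi1 = round(eul$phi1 * d2r, 8),
                     PHI = round(eul$Phi * d2r, 8),
                     phi2 = round(eul$phi2 * d2r, 8),
                     x = (xi - 1L) * step, y = (yi - 1L) * step,
                     iq = 100, ci = ifelse(indexed, 1, -1), phase = 1L)
    utils::write.table(df, con, sep = " ", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a ground-truth label grid as CSV
#'
#' Sidecar for [generateMap()]: a height x width integer grid of grain ids.
#'
#' @param labels integer matrix.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeLabelGrid <- function(labels, path) {
  utils::write.table(labels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

## ---- run configuration ----------------------------------------------

.configDefaults <- list(
  seg_threshold_deg = 10, seg_connectivity = 8L, seg_min_pixels = 5L,
  seg_merge_small = TRUE,
  md_bin_width_deg = 5, md_n_random_pairs = NA_integer_, md_seed = NA_integer_,
  md_type1_threshold = 0.50, md_weak_threshold = 0.35,
  ar_percentile_filter = TRUE, ar_bin_width = 0.5,
  gb_floor_deg = 2, gb_n_depth_bins = 10L,
  phylo_transform = "log", phylo_delta_aicc = 2,
  phylo_models = c("BM", "OU", "EB", "Trend", "Lambda", "WhiteNoise"))

#' Build a run configuration
#'
#' All defaults are materialised so that the run log can echo every
#' parameter actually used. Unknown keys are an error (a silent typo would
#' corrupt the analysis), and a seed is mandatory whenever a stochastic
#' stage (random-pair sampling) will run.
#'
#' @param ... overrides of the default keys (see
#'   \code{eggshellEBSD:::.configDefaults}).
#' @return a named list with class "runConfig".
#' @export
runConfig <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.configDefaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.configDefaults, over)
  class(cfg) <- "runConfig"
  cfg
}

.logLine <- function(con, stage, ...) {
  kv <- list(...)
  msg <- paste0(stage, ": ",
                paste(names(kv), vapply(kv, function(v)
                  paste(format(v, digits = 10), collapse = ","), ""),
                  sep = "=", collapse = " "))
  if (!is.null(con)) writeLines(msg, con)
  invisible(msg)
}

#' Run the full map-analysis pipeline
#'
#' Segments the map, classes its boundaries, builds the depth profile of
#' low-angle boundary fraction, computes neighbour- and random-pair
#' misorientation distributions with the Type 1 / Type 2 verdict, and the
#' filtered aspect-ratio summary. When \code{outDir} is given, every
#' product is written (grain CSV, MD CSV + JSON, AR summary JSON, GB
#' profile CSV, run log); outputs are deterministic given the config.
#'
#' @param map an \linkS4class{OrientationMap} or a path to a CTF/ANG file.
#' @param config a [runConfig()].
#' @param outDir output directory (NULL = no files written).
#' @param dialect file dialect when \code{map} is a path.
#' @return list: grains, segments, gbProfile, mdNeighbour, mdRandom,
#'   mdClass, arSummary, config.
#' @export
runPipeline <- function(map, config = runConfig(), outDir = NULL,
                        dialect = "ctf") {
  if (is.character(map)) {
    if (!file.exists(map)) stop("missing input path: ", map)
    map <- readOrientationMap(map, dialect)
  }
  if (is.na(config$md_seed))
    stop("config must set md_seed (random-pair sampling is stochastic)")
  log <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    log <- file(file.path(outDir, "run.log"), "w")
    on.exit(close(log))
    for (k in names(unclass(config)))
      .logLine(log, "config", key = k, value = config[[k]])
  }
  grains <- segmentGrains(map, thresholdDeg = config$seg_threshold_deg,
                          connectivity = config$seg_connectivity,
                          minPixels = config$seg_min_pixels,
                          mergeSmall = config$seg_merge_small)
  .logLine(log, "segment", n_grains = nGrains(grains),
           threshold_deg = config$seg_threshold_deg)
  segments <- boundarySegments(grains, floorDeg = config$gb_floor_deg)
  gbProfile <- gbDepthProfile(grains, segments,
                              nBins = config$gb_n_depth_bins)
  .logLine(log, "boundaries", n_segments = nrow(segments))
  mdN <- neighbourPairMD(grains, binWidthDeg = config$md_bin_width_deg)
  nRand <- if (is.na(config$md_n_random_pairs)) NULL else config$md_n_random_pairs
  mdR <- randomPairMD(grains, nPairs = nRand, seed = config$md_seed,
                      binWidthDeg = config$md_bin_width_deg)
  cls <- classifyMD(mdN, type1 = config$md_type1_threshold,
                    weak = config$md_weak_threshold)
  .logLine(log, "md", mean_neighbour = mdMean(mdN), mean_random = mdMean(mdR),
           frac_below_20 = mdFracBelow20(mdN), class = cls$label,
           seed = config$md_seed)
  ars <- arSummary(grains, binWidth = config$ar_bin_width,
                   filter = config$ar_percentile_filter)
  .logLine(log, "ar", mean_ar = ars$meanAR, n_retained = ars$n_retained)
  if (!is.null(outDir)) {
    writeGrainCsv(grains, file.path(outDir, "grains.csv"))
    writeMD(mdN, file.path(outDir, "md_neighbour.csv"),
            file.path(outDir, "md_neighbour.json"), class = cls)
    writeMD(mdR, file.path(outDir, "md_random.csv"),
            file.path(outDir, "md_random.json"))
    utils::write.csv(gbProfile, file.path(outDir, "gb_profile.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(mean_ar = ars$meanAR, skewness = ars$skewness,
                              n_retained = ars$n_retained,
                              n_total = ars$n_total),
                         file.path(outDir, "ar_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    for (f in c("grains.csv", "md_neighbour.csv", "md_neighbour.json",
                "md_random.csv", "md_random.json", "gb_profile.csv",
                "ar_summary.json"))
      .logLine(log, "output", file = f,
               md5 = unname(tools::md5sum(file.path(outDir, f))))
  }
  list(grains = grains, segments = segments, gbProfile = gbProfile,
       mdNeighbour = mdN, mdRandom = mdR, mdClass = cls,
       arSummary = ars, config = config)
}

#' Run the phylogenetic comparative analysis
#'
#' Log-transforms the trait means (per config), estimates Pagel's lambda,
#' fits the configured evolutionary models with AICc selection, and
#' performs ML BM ancestral state reconstruction only when BM is the best
#' model or within delta AICc of it; otherwise the reconstruction is
#' suppressed with an explanatory verdict.
#'
#' @param traits named numeric vector of per-species trait means (raw
#'   scale), or a path to a CSV with columns species, value.
#' @param tree an \code{ape::phylo} tree, or a path to a Newick file.
#' @param config a [runConfig()].
#' @param outDir output directory (NULL = no files written).
#' @param substitutions optional named character vector of tip relabels
#'   applied to the tree first (old -> new).
#' @return list: lambda (fitPagelLambda result), fits, selection, asr (an
#'   \linkS4class{AncestralReconstruction} or NULL), verdict, traitsLog.
#' @export
runComparative <- function(traits, tree, config = runConfig(), outDir = NULL,
                           substitutions = NULL) {
  if (is.character(traits)) {
    if (!file.exists(traits)) stop("missing input path: ", traits)
    df <- utils::read.csv(traits)
    if (!all(c("species", "value") %in% names(df)))
      stop("trait CSV must have columns species, value")
    traits <- stats::setNames(df$value, df$species)
  }
  if (is.character(tree)) {
    if (!file.exists(tree)) stop("missing input path: ", tree)
    tree <- ape::read.tree(tree)
  }
  if (!is.null(substitutions)) tree <- graftSubstituteTips(tree, substitutions)
  useLog <- identical(config$phylo_transform, "log")
  if (useLog) {
    if (any(traits <= 0)) stop("trait values must be positive for the log transform")
    x <- log(traits)
  } else x <- traits
  x <- .checkTraits(tree, x)
  lam <- fitPagelLambda(tree, x)
  fits <- lapply(config$phylo_models, function(m) fitEvoModel(tree, x, m))
  sel <- selectModel(fits, delta = config$phylo_delta_aicc)
  asr <- NULL
  verdict <- if (sel$bmAsGood) {
    sprintf("BM %s (deltaAICc = %.3f): ancestral reconstruction performed",
            if (sel$best == "BM") "is the best model" else "is as good as the best model",
            sel$table$deltaAICc[sel$table$model == "BM"])
  } else {
    sprintf("best model is %s and BM is not within delta AICc = %g: ancestral reconstruction not performed",
            sel$best, config$phylo_delta_aicc)
  }
  if (sel$bmAsGood)
    asr <- asrBM(tree, x, backTransform = if (useLog) exp else identity)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    fitList <- lapply(fits, function(f)
      list(model = f@model, params = f@params, logLik = f@logLik,
           k = f@k, AICc = f@AICc, converged = f@converged))
    jsonlite::write_json(
      list(lambda = lam$lambda, lambda_logLik = lam$logLik,
           n = length(x), transform = config$phylo_transform,
           fits = fitList, best = sel$best, as_good = sel$asGood,
           verdict = verdict),
      file.path(outDir, "model_fits.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(asr))
      utils::write.csv(asrStates(asr), file.path(outDir, "asr.csv"),
                       row.names = FALSE)
  }
  list(lambda = lam, fits = fits, selection = sel, asr = asr,
       verdict = verdict, traitsLog = x)
}
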