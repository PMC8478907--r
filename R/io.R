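# File formats, configuration, and the pipeline driver.
#
# Formats: FASTA for sequences (single record, treated as circular),
# CSV for all tables, JSON for reports.  Every writer's output is
# re-readable by the matching reader, and all randomness flows from
# seeds in the configuration so that reports are reproducible
# byte-for-byte.

#' Load a circular sequence from a FASTA file
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @param circular Must be `TRUE`; present to make the circularity
#'   assumption explicit at call sites.
#' @return A [circular_sequence()] named after the FASTA header.
#' @export
load_sequence <- function(path, circular = TRUE) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (!isTRUE(circular))
    stop("only circular sequences are supported here", call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L)
    stop("format error: no FASTA record in ", path, call. = FALSE)
  if (length(set) > 1L)
    stop("format error: expected exactly one FASTA record, found ",
         length(set), " in ", path, call. = FALSE)
  circular_sequence(as.character(set[[1L]]), name = names(set)[1L])
}

#' Packaged minicircle sequences
#'
#' Returns one of the minicircle sequences used throughout the
#' examples. The 336 bp sequence is shipped as a FASTA fixture; the
#' 333 bp variant carries a 3 bp net deletion (TGTATGGCATGAA ->
#' TGTATATGAA) and the 339 bp variant a 3 bp net insertion
#' (TGTATGGCATGAA -> TGTATGGCGAAATGAA), both applied in code. The
#' double-length 666 and 672 bp circles are two tandem copies of the
#' 333 and 336 bp sequences.
#'
#' @param size One of `"336"`, `"333"`, `"339"`, `"666"`, `"672"`.
#' @return A [circular_sequence()] of the requested size.
#' @examples
#' minicircle_sequence("336")
#' @export
minicircle_sequence <- function(size = c("336", "333", "339", "666", "672")) {
  size <- match.arg(as.character(size), c("336", "333", "339", "666", "672"))
  base <- load_sequence(system.file("extdata", "minicircle_336.fa",
                                    package = "minicircletools", mustWork = TRUE))
  b336 <- base$bases
  b333 <- sub("TGTATGGCATGAA", "TGTATATGAA", b336, fixed = TRUE)
  b339 <- sub("TGTATGGCATGAA", "TGTATGGCGAAATGAA", b336, fixed = TRUE)
  bases <- switch(size,
                  "336" = b336, "333" = b333, "339" = b339,
                  "666" = paste0(b333, b333), "672" = paste0(b336, b336))
  circular_sequence(bases, name = paste0("minicircle_", size))
}

## ---- CSV dialects --------------------------------------------------------

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop("format error in ", what, " table '", path, "': missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read / write the CSV dialects used by the pipeline
#'
#' Mobility tables: `construct_id, size_bp, lk, mobility`.
#' Fragment observations: `reference_enzyme, length_bp` plus optional
#' `length_sd_bp`, `band_volume`.
#' Time courses: `species, time_s, uncut_fraction`.
#' Rate profiles: `sigma, k` plus optional `k_stderr`.
#'
#' @param path CSV file path.
#' @return The validated data.frame.
#' @name csv_io
NULL

#' @rdname csv_io
#' @export
read_mobility_csv <- function(path)
  read_table_checked(path, c("construct_id", "size_bp", "lk", "mobility"),
                     "mobility")

#' @rdname csv_io
#' @export
read_observations_csv <- function(path) {
  df <- read_table_checked(path, c("reference_enzyme", "length_bp"),
                           "fragment-observation")
  if (!"length_sd_bp" %in% names(df)) df$length_sd_bp <- 10
  df
}

#' @rdname csv_io
#' @export
read_timecourse_csv <- function(path)
  read_table_checked(path, c("species", "time_s", "uncut_fraction"),
                     "time-course")

#' @rdname csv_io
#' @export
read_profile_csv <- function(path)
  read_table_checked(path, c("sigma", "k"), "rate-profile")

#' @rdname csv_io
#' @param df Data.frame to write.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- configuration and pipeline ------------------------------------------

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the pipeline with its default:
#' helical repeats (`h_B` 10.48 bp/turn under the nuclease reaction
#' buffer, `h_P` 3), mapping parameters (cluster threshold 15 bp,
#' minimum support 2 enzymes), kinetics parameters (initial-window
#' fraction threshold 0.5, minimum 3 points, threshold fold 5), and the
#' simulation seed. All values are range-checked on construction.
#'
#' @param h_B,h_P Helical repeats, bp/turn (see [helix_params()]).
#' @param cluster_threshold_bp,min_support Mapping parameters (see
#'   [triangulate_sites()]).
#' @param fraction_min,min_points,min_fold Kinetics parameters (see
#'   [fit_initial_rate()], [detect_threshold()]).
#' @param seed Integer seed for any simulated inputs.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(h_B = 10.48, h_P = 3, cluster_threshold_bp = 15,
                       min_support = 2, fraction_min = 0.5, min_points = 3,
                       min_fold = 5, seed = 1) {
  helix <- helix_params(h_B, h_P)  # validates the repeats
  if (cluster_threshold_bp <= 0) stop("'cluster_threshold_bp' must be > 0",
                                      call. = FALSE)
  if (min_support < 1) stop("'min_support' must be >= 1", call. = FALSE)
  if (fraction_min <= 0 || fraction_min > 1)
    stop("'fraction_min' must be in (0, 1]", call. = FALSE)
  if (min_points < 2) stop("'min_points' must be >= 2", call. = FALSE)
  if (min_fold <= 1) stop("'min_fold' must be > 1", call. = FALSE)
  structure(list(h_B = helix$h_B, h_P = helix$h_P,
                 cluster_threshold_bp = cluster_threshold_bp,
                 min_support = min_support, fraction_min = fraction_min,
                 min_points = as.integer(min_points), min_fold = min_fold,
                 seed = as.integer(seed)),
            class = "run_config")
}

round_sig <- function(x, digits) ifelse(is.finite(x), signif(x, digits), x)

#' Run the analysis pipeline on a bundle of inputs
#'
#' Executes the requested stages in order — helical-repeat calibration,
#' topology table, cleavage-site mapping, kinetics — and assembles a
#' JSON-serialisable report. Any subset of inputs may be supplied;
#' stages without inputs are skipped. When calibration is run its
#' pooled helical repeat supersedes `config$h_B` for the topology
#' stage, mirroring how a calibrated repeat is used to compute the
#' superhelical densities that are then reported.
#'
#' Reported numbers carry conventional display precision (Lk0 2
#' decimals, sigma 3 decimals, rates 3 significant figures) in `display`
#' fields while full-precision values are retained alongside.
#'
#' @param config A [run_config()].
#' @param inputs A list with any of:
#'   \describe{
#'     \item{mobility}{data.frame or CSV path (mobility dialect).}
#'     \item{topology}{list with `size_bp` and `lks` for the topology
#'       table.}
#'     \item{sequence}{a [circular_sequence()] or FASTA path, used with
#'       `enzymes` (character vector, default the built-in five cutters)
#'       and `observations` (data.frame or CSV path) for site mapping.}
#'     \item{timecourses}{data.frame or CSV path (time-course dialect);
#'       one initial-rate fit per species.}
#'     \item{profile}{data.frame or CSV path (rate-profile dialect) for
#'       threshold detection, with optional `profile_side`.}
#'   }
#' @param out_dir If non-NULL, the report is written to
#'   `report.json` and each tabular stage to a CSV in this directory.
#' @return The report, a named list (invisibly if `out_dir` is given).
#' @export
run_pipeline <- function(config, inputs, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  report <- list(parameters = unclass(config))
  tables <- list()
  h_B <- config$h_B

  if (!is.null(inputs$mobility)) {
    mob <- if (is.character(inputs$mobility)) read_mobility_csv(inputs$mobility)
           else inputs$mobility
    cal <- tryCatch(calibrate_helical_repeat(mob),
                    error = function(e) stop("stage 'calibrate': ",
                                             conditionMessage(e), call. = FALSE))
    h_B <- cal$h_mean
    report$calibration <- list(
      h_mean = cal$h_mean, h_sd = cal$h_sd,
      display = list(h_mean = round(cal$h_mean, 2)),
      per_construct = cal$per_construct)
    tables$calibration <- cal$per_construct
  }

  if (!is.null(inputs$topology)) {
    tp <- inputs$topology
    tab <- topoisomer_table(tp$size_bp, tp$lks,
                            helix_params(h_B = h_B, h_P = config$h_P))
    disp <- tab
    disp$lk0 <- round(disp$lk0, 2)
    disp$dlk_exact <- round(disp$dlk_exact, 2)
    disp$sigma <- round(disp$sigma, 3)
    report$topology <- list(h_B_used = h_B, table = tab, display = disp)
    tables$topology <- disp
  }

  if (!is.null(inputs$sequence) && !is.null(inputs$observations)) {
    seqc <- if (is.character(inputs$sequence)) load_sequence(inputs$sequence)
            else inputs$sequence
    enz <- if (is.null(inputs$enzymes))
             c("EcoRV", "XmnI", "BbvCI", "NdeI", "MseI") else inputs$enzymes
    rmap <- restriction_map(seqc, enz)
    obs <- if (is.character(inputs$observations))
             read_observations_csv(inputs$observations) else inputs$observations
    est <- tryCatch(
      triangulate_sites(obs, rmap,
                        cluster_threshold = config$cluster_threshold_bp,
                        min_support = config$min_support),
      error = function(e) stop("stage 'map-sites': ", conditionMessage(e),
                               call. = FALSE))
    report$mapping <- list(sequence = seqc$name, n_cuts = nrow(rmap$entries),
                           estimates = as.data.frame(est))
    tables$sites <- as.data.frame(est)
  }

  if (!is.null(inputs$timecourses)) {
    tcs <- if (is.character(inputs$timecourses))
             read_timecourse_csv(inputs$timecourses) else inputs$timecourses
    fits <- lapply(split(tcs, tcs$species), function(df) {
      df <- df[order(df$time_s), , drop = FALSE]
      fit <- fit_initial_rate(time_course(df$time_s, df$uncut_fraction,
                                          species = df$species[1L]),
                              fraction_min = config$fraction_min,
                              min_points = config$min_points)
      data.frame(species = df$species[1L], k = fit$k, stderr = fit$stderr,
                 n_used = fit$n_used, k_display = round_sig(fit$k, 3))
    })
    rates <- do.call(rbind, fits)
    rownames(rates) <- NULL
    report$kinetics <- list(rates = rates)
    tables$rates <- rates
  }

  if (!is.null(inputs$profile)) {
    prof <- if (is.character(inputs$profile)) read_profile_csv(inputs$profile)
            else inputs$profile
    side <- if (is.null(inputs$profile_side)) "negative" else inputs$profile_side
    thr <- detect_threshold(rate_profile(prof$sigma, prof$k),
                            min_fold = config$min_fold, side = side)
    report$threshold <- if (is.null(thr)) list(found = FALSE)
      else list(found = TRUE, sigma_low = thr$sigma_low,
                sigma_high = thr$sigma_high, fold_change = thr$fold_change)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(tables))
      write_table_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    return(invisible(report))
  }
  report
}
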