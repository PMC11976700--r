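# Plain-text readers and writers for the tabular formats the pipeline
# exchanges. All CSVs: comma separator, header row, "." decimal, UTF-8.

#' Read a two-wavelength plate CSV
#'
#' Expected columns: `well`, `time_s`, `A616`, `A499` (reporter and
#' isosbestic absorbances).
#'
#' @param path File path.
#' @return Named list of [well_timeseries()], one per well.
#' @export
read_plate_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "time_s", "A616", "A499")
  if (!all(need %in% names(d)))
    halocat_error(sprintf("plate CSV must have columns: %s",
                          paste(need, collapse = ", ")),
                  "halocat_invalid_parameter")
  lapply(split(d, d$well), function(w) {
    w <- w[order(w$time_s), ]
    well_timeseries(w$well[1], w$time_s, w$A616, w$A499)
  })
}

#' Write well time series to a plate CSV
#'
#' @param wells List of [well_timeseries()] (or a single one).
#' @param path File path.
#' @export
write_plate_csv <- function(wells, path) {
  if (inherits(wells, "well_timeseries")) wells <- list(wells)
  rows <- do.call(rbind, lapply(wells, function(w)
    data.frame(well = attr(w, "well_id"), time_s = w$time_s,
               A616 = w$a_report, A499 = w$a_iso)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a chiral-GC conversion/ee table
#'
#' Expected columns: `sample`, `conversion_pct`, `ee_s_pct`, `ee_p_pct`,
#' `preferred` (percent columns; ee_s may be NA).
#'
#' @param path File path.
#' @return Data frame with fraction-valued `conversion`, `ee_s`, `ee_p`.
#' @export
read_gc_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "conversion_pct", "ee_p_pct")
  if (!all(need %in% names(d)))
    halocat_error("GC table must have columns sample, conversion_pct, ee_p_pct",
                  "halocat_invalid_parameter")
  data.frame(sample = d$sample,
             conversion = d$conversion_pct / 100,
             ee_s = if ("ee_s_pct" %in% names(d)) d$ee_s_pct / 100 else NA_real_,
             ee_p = d$ee_p_pct / 100,
             preferred = if ("preferred" %in% names(d)) d$preferred else "")
}

#' Write resolution observations as a GC-style table
#'
#' @param obs Data frame with `conversion`, `ee_s`, `ee_p`, `preferred`,
#'   `label` (fractions), e.g. rows from [simulate_resolution_outcome()].
#' @param path File path.
#' @export
write_gc_table <- function(obs, path) {
  utils::write.csv(data.frame(sample = obs$label,
                              conversion_pct = obs$conversion * 100,
                              ee_s_pct = obs$ee_s * 100,
                              ee_p_pct = obs$ee_p * 100,
                              preferred = obs$preferred),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a melt-curve CSV (`temp_C`, `fluorescence`, optional `well`)
#'
#' @param path File path.
#' @return Named list of [melt_curve()]s (single unnamed curve when no
#'   `well` column).
#' @export
read_melt_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("temp_C", "fluorescence") %in% names(d)))
    halocat_error("melt CSV must have columns temp_C, fluorescence",
                  "halocat_invalid_parameter")
  if (!"well" %in% names(d)) d$well <- "curve"
  lapply(split(d, d$well), function(w) {
    w <- w[order(w$temp_C), ]
    melt_curve(w$temp_C, w$fluorescence, label = w$well[1])
  })
}

#' Write a melt curve CSV
#' @param curve A [melt_curve()].
#' @param path File path.
#' @export
write_melt_csv <- function(curve, path) {
  utils::write.csv(data.frame(temp_C = curve$temp_c,
                              fluorescence = curve$fluorescence),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a progress curve CSV (`time_s`, `product_mM`, `uncertainty_mM`)
#' @param curve A [progress_curve()] or list of them.
#' @param path File path.
#' @export
write_progress_csv <- function(curve, path) {
  if (inherits(curve, "progress_curve")) curve <- list(curve)
  rows <- do.call(rbind, lapply(curve, function(cc)
    data.frame(sample = attr(cc, "label"), time_s = cc$time_s,
               product_mM = cc$product, uncertainty_mM = cc$uncertainty)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a coordinate ensemble
#'
#' Two formats: a whitespace-separated plain table with one row per frame
#' and 3n columns (x1 y1 z1 x2 y2 z2 ...), or a multi-model PDB from which
#' Calpha coordinates are extracted per model (requires the bio3d package).
#'
#' @param path File path (`.pdb` routes to the PDB reader).
#' @return A [coordinate_ensemble()].
#' @export
read_ensemble <- function(path) {
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    if (!requireNamespace("bio3d", quietly = TRUE))
      halocat_error("reading PDB ensembles requires the bio3d package",
                    "halocat_invalid_parameter")
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    sel <- bio3d::atom.select(pdb, "calpha")
    xyz <- pdb$xyz[, sel$xyz, drop = FALSE]  # frames x 3n
    nres <- length(sel$atom)
    labels <- paste0(pdb$atom$resid[sel$atom], pdb$atom$resno[sel$atom])
  } else {
    xyz <- as.matrix(utils::read.table(path))
    if (ncol(xyz) %% 3 != 0)
      halocat_error("ensemble table must have 3n coordinate columns",
                    "halocat_invalid_parameter")
    nres <- ncol(xyz) / 3
    labels <- NULL
  }
  frames <- array(0, c(nrow(xyz), nres, 3))
  for (a in 1:3) frames[, , a] <- xyz[, seq(a, by = 3, length.out = nres)]
  coordinate_ensemble(frames, labels)
}

#' Write a coordinate ensemble as a plain frames table
#' @param ensemble A [coordinate_ensemble()].
#' @param path File path.
#' @export
write_ensemble_table <- function(ensemble, path) {
  nf <- dim(ensemble$frames)[1]; n <- dim(ensemble$frames)[2]
  flat <- matrix(0, nf, 3 * n)
  for (a in 1:3) flat[, seq(a, by = 3, length.out = n)] <- ensemble$frames[, , a]
  utils::write.table(flat, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an SPM edge list CSV (`res_i`, `res_j`, `weight`, `usage`,
#' `in_map`)
#' @param graph A [shortest_path_map()] (or [build_spm_graph()]) result.
#' @param path File path.
#' @export
write_edge_csv <- function(graph, path) {
  e <- graph$edges
  utils::write.csv(data.frame(res_i = graph$nodes[e$i],
                              res_j = graph$nodes[e$j],
                              weight = e$weight, usage = e$usage,
                              in_map = e$in_map),
                   path, row.names = FALSE)
  invisible(path)
}
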