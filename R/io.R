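fmt_num <- function(x) sprintf("%.17g", x)

#' Write detector geometry
#'
#' Plain-text panel dialect, one block per panel:
#' \preformatted{
#' panel panel0
#'   fs = 7.5e-05 0 0
#'   ss = 0 7.5e-05 0
#'   corner = -0.0075 -0.0075 0.1
#'   npix = 200 200
#'   gain = 1
#' }
#' `fs`/`ss` are the lab displacements per pixel step (m), `corner` the
#' lab position of the (0,0) pixel corner. Numbers are written with 17
#' significant digits so a read/write round trip is exact.
#'
#' @param geometry A [detector_geometry()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  lines <- character(0)
  for (p in geometry$panels) {
    lines <- c(lines,
               paste("panel", p$name),
               paste("  fs =", paste(fmt_num(p$D[, 1]), collapse = " ")),
               paste("  ss =", paste(fmt_num(p$D[, 2]), collapse = " ")),
               paste("  corner =",
                     paste(fmt_num(p$origin), collapse = " ")),
               paste("  npix =", p$n_fs, p$n_ss),
               paste("  gain =", fmt_num(p$gain)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read detector geometry
#'
#' Parses the panel dialect of [write_geometry()]. Malformed keys or
#' incomplete panels raise an error naming the offending line.
#'
#' @param path Geometry file.
#' @return A [detector_geometry()].
#' @export
read_geometry <- function(path) {
  lines <- readLines(path)
  panels <- list()
  cur <- NULL
  finish <- function(cur) {
    need <- c("fs", "ss", "corner", "npix", "gain")
    miss <- setdiff(need, names(cur$fields))
    if (length(miss)) {
      stop("panel '", cur$name, "' is missing key(s): ",
           paste(miss, collapse = ", "))
    }
    f <- cur$fields
    panel(D = cbind(f$fs, f$ss), origin = f$corner, n_fs = f$npix[1],
          n_ss = f$npix[2], gain = f$gain, name = cur$name)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(ln, "panel ")) {
      if (!is.null(cur)) panels[[length(panels) + 1L]] <- finish(cur)
      cur <- list(name = trimws(sub("^panel ", "", ln)), fields = list())
      next
    }
    if (is.null(cur) || !grepl("=", ln, fixed = TRUE)) {
      stop("malformed geometry line ", i, ": '", lines[i], "'")
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- suppressWarnings(as.numeric(strsplit(trimws(kv[2]),
                                                "\\s+")[[1]]))
    nexp <- c(fs = 3, ss = 3, corner = 3, npix = 2, gain = 1)
    if (!key %in% names(nexp)) {
      stop("unknown geometry key '", key, "' at line ", i)
    }
    if (length(val) != nexp[[key]] || anyNA(val)) {
      stop("malformed value for '", key, "' at line ", i)
    }
    cur$fields[[key]] <- val
  }
  if (!is.null(cur)) panels[[length(panels) + 1L]] <- finish(cur)
  if (!length(panels)) stop("no panels found in ", path)
  detector_geometry(panels)
}

OBS_COLUMNS <- c("crystal_id", "h", "k", "l", "intensity", "sigma",
                 "panel", "fs", "ss")

#' Write an observation table
#'
#' Whitespace-delimited text with a header line; the documented columns
#' come first, any extra columns are preserved verbatim after them.
#'
#' @param observations `data.frame` containing at least the columns
#'   `crystal_id h k l intensity sigma panel fs ss`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  miss <- setdiff(OBS_COLUMNS, names(observations))
  if (length(miss)) {
    stop("observation table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(observations), OBS_COLUMNS)
  data.table::fwrite(observations[, c(OBS_COLUMNS, extra)], path,
                     sep = " ", quote = FALSE)
  invisible(path)
}

#' Read an observation table
#'
#' @param path File written by [write_observations()] (or any
#'   whitespace-delimited table with the documented header).
#' @return `data.frame` with the documented columns (extra columns
#'   preserved).
#' @export
read_observations <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = " ",
                          data.table = FALSE)
  miss <- setdiff(OBS_COLUMNS, names(dt))
  if (length(miss)) {
    stop("observation table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  dt
}

#' Write a merged-intensity table
#'
#' Columns `h k l I_merged sigma_merged n_obs`, whitespace-delimited with
#' a header, column-compatible with common merged-reflection text layouts.
#'
#' @param merged `data.frame` from [merged_table()] or
#'   [monte_carlo_merge()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_merged <- function(merged, path) {
  data.table::fwrite(merged, path, sep = " ", quote = FALSE)
  invisible(path)
}

#' Write a set of panel images as plain text
#'
#' Simple hierarchical array container: a magic line, then one
#' `array <name> <n_fs> <n_ss>` header per panel followed by `n_ss` lines
#' of `n_fs` numbers (readings for `ss` fixed per line).
#'
#' @param images Named list of matrices (`n_fs x n_ss`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_image_set <- function(images, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("stillgauss-images 1", con)
  for (nm in names(images)) {
    m <- images[[nm]]
    writeLines(paste("array", nm, nrow(m), ncol(m)), con)
    writeLines(apply(m, 2, function(col) {
      paste(fmt_num(col), collapse = " ")
    }), con)
  }
  invisible(path)
}

#' Read a set of panel images
#'
#' @param path File written by [write_image_set()].
#' @return Named list of matrices.
#' @export
read_image_set <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "stillgauss-images")) {
    stop(path, " is not an image-set file")
  }
  out <- list()
  i <- 2L
  while (i <= length(lines)) {
    hd <- strsplit(lines[i], "\\s+")[[1]]
    if (hd[1] != "array" || length(hd) != 4) {
      stop("malformed array header at line ", i)
    }
    nfs <- as.integer(hd[3])
    nss <- as.integer(hd[4])
    vals <- as.numeric(unlist(strsplit(lines[(i + 1):(i + nss)], " ")))
    out[[hd[2]]] <- matrix(vals, nrow = nfs, ncol = nss)
    i <- i + nss + 1L
  }
  out
}

#' Write per-crystal model parameters
#'
#' One row per crystal: the reciprocal cell serialized row-major as three
#' basis vectors (`a1 a2 a3 b1 ... c3`, matching the row-vector convention
#' of the dialects), the six upper-triangle entries of the shape
#' covariance, mosaicity, strain, scale and B factor.
#'
#' @param crystals List of [crystal_model()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_crystal_models <- function(crystals, path) {
  rows <- lapply(seq_along(crystals), function(i) {
    cr <- crystals[[i]]
    Rt <- t(cr$R)  # rows = basis vectors
    s <- cr$shape_cov
    data.frame(crystal_id = i,
               a1 = Rt[1, 1], a2 = Rt[1, 2], a3 = Rt[1, 3],
               b1 = Rt[2, 1], b2 = Rt[2, 2], b3 = Rt[2, 3],
               c1 = Rt[3, 1], c2 = Rt[3, 2], c3 = Rt[3, 3],
               s11 = s[1, 1], s12 = s[1, 2], s13 = s[1, 3],
               s22 = s[2, 2], s23 = s[2, 3], s33 = s[3, 3],
               mosaicity = cr$mosaicity, strain = cr$strain,
               scale_a = cr$scale_a, b_factor = cr$b_factor)
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = " ",
                     quote = FALSE)
  invisible(path)
}

#' Read per-crystal model parameters
#'
#' @param path File written by [write_crystal_models()].
#' @return List of [crystal_model()] objects ordered by `crystal_id`.
#' @export
read_crystal_models <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  dt <- dt[order(dt$crystal_id), ]
  lapply(seq_len(nrow(dt)), function(i) {
    r <- dt[i, ]
    Rt <- rbind(c(r$a1, r$a2, r$a3), c(r$b1, r$b2, r$b3),
                c(r$c1, r$c2, r$c3))
    s <- matrix(c(r$s11, r$s12, r$s13,
                  r$s12, r$s22, r$s23,
                  r$s13, r$s23, r$s33), 3, 3)
    crystal_model(R = t(Rt), shape_cov = s, mosaicity = r$mosaicity,
                  strain = r$strain, scale_a = r$scale_a,
                  b_factor = r$b_factor)
  })
}

RUN_CONFIG_SCHEMA <- list(
  beam = c("nu0", "wavelength", "bandwidth", "divergence", "polarization",
           "pol_normal", "flux"),
  crystal = c("cell_nm", "shape_sigma", "mosaicity", "strain", "scale_a",
              "b_factor"),
  geometry = "path",
  cutoffs = c("sigma_cutoff", "d_min", "ellipse_sigma"),
  optimizer = c("maxit", "tol"),
  error_model = c("alpha", "beta", "epsilon", "outlier_scale"),
  outliers = c("gamma"),
  simulate = c("n_crystals", "wilson_mean", "scale_sdlog",
               "outlier_fraction", "crystal_size_nm", "counting_floor",
               "b_factor_mean", "b_factor_sd"),
  seed = NULL,
  verbosity = NULL)

#' Read a run configuration
#'
#' YAML configuration with the documented sections (`beam`, `crystal`,
#' `geometry`, `cutoffs`, `optimizer`, `error_model`, `outliers`,
#' `simulate`, `seed`, `verbosity`). Unknown keys are rejected with an
#' error naming them, so typos cannot silently fall back to defaults.
#'
#' @param path YAML file.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown_top <- setdiff(names(cfg), names(RUN_CONFIG_SCHEMA))
  if (length(unknown_top)) {
    stop("unknown config key(s): ", paste(unknown_top, collapse = ", "))
  }
  for (sec in names(cfg)) {
    allowed <- RUN_CONFIG_SCHEMA[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad)) {
      stop("unknown config key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    }
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#'
#' @param cfg Named list (validated against the documented schema).
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
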