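#' Write / read a cell trace as CSV
#'
#' Plain-text round-trip of the sampled series with header
#' `t_ms,V_mV,Ca_sub_mM,Ca_cen_mM`; stimulus onsets are kept in a comment
#' line so the file reloads as a measurable trace.
#'
#' @param trace a `cell_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# stim_times_ms: ",
                    paste(trace$stim_times, collapse = " ")), con)
  writeLines("t_ms,V_mV,Ca_sub_mM,Ca_cen_mM", con)
  utils::write.table(
    data.frame(trace$t, trace$V, trace$Ca_sub, trace$Ca_cen),
    con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1)
  stim <- numeric(0)
  skip <- 0
  if (startsWith(first, "# stim_times_ms:")) {
    stim <- as.numeric(strsplit(sub("# stim_times_ms: *", "", first),
                                " +")[[1]])
    stim <- stim[!is.na(stim)]
    skip <- 1
  }
  d <- utils::read.csv(path, skip = skip)
  structure(list(t = d$t_ms, V = d$V_mV, Ca_sub = d$Ca_sub_mM,
                 Ca_cen = d$Ca_cen_mM, stim_times = stim,
                 final_state = NULL, max_dvdt = NA_real_),
            class = "cell_trace")
}

#' Write / read a full state snapshot (restart format)
#'
#' Key = value text format, one state variable per line, suitable for
#' restarting a simulation.
#'
#' @param state a `membrane_state`.
#' @param path file path.
#' @return `path` / the reloaded `membrane_state`.
#' @export
write_state <- function(state, path) {
  state <- validate_state(state)
  writeLines(sprintf("%s = %.17g", names(state), as.numeric(state)), path)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  ln <- readLines(path)
  kv <- strsplit(ln, " *= *")
  s <- vapply(kv, function(x) as.numeric(x[2]), numeric(1))
  names(s) <- vapply(kv, `[[`, "", 1)
  s <- s[as.character(state_names())]
  validate_state(structure(s, class = "membrane_state"))
}

#' Write / read a geometry container
#'
#' Flat-text container: a header of `key = value` lines (dims, dx,
#' diffusion coefficients, periodicity) followed by per-voxel records
#' (inside flag, region label, fibre vector).
#'
#' @param geom an `atrial_geometry`.
#' @param path file path.
#' @return `path` / the reloaded geometry.
#' @export
write_geometry <- function(geom, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("dims =", paste(geom$dims, collapse = " ")),
    paste("dx =", format(geom$dx, digits = 17)),
    paste("d_iso =", format(geom$d_iso, digits = 17)),
    paste("d_long =", format(geom$d_long, digits = 17)),
    paste("d_trans =", format(geom$d_trans, digits = 17)),
    paste("periodic =", as.integer(geom$periodic)),
    paste("has_fibre =", as.integer(!is.null(geom$fibre))),
    "voxels: inside region fx fy fz"), con)
  nf <- if (is.null(geom$fibre)) matrix(0, prod(geom$dims), 3) else geom$fibre
  utils::write.table(
    data.frame(as.integer(geom$inside), geom$region,
               nf[, 1], nf[, 2], nf[, 3]),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  ln <- readLines(path)
  hdr_end <- which(startsWith(ln, "voxels:"))[1]
  kv <- strsplit(ln[seq_len(hdr_end - 1)], " *= *")
  h <- stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
  d <- utils::read.table(text = ln[-seq_len(hdr_end)],
                         col.names = c("inside", "region", "fx", "fy", "fz"),
                         colClasses = c("integer", "character", "numeric",
                                        "numeric", "numeric"))
  fib <- as.matrix(d[, c("fx", "fy", "fz")])
  dimnames(fib) <- NULL
  .new_geometry(dims = as.integer(strsplit(h$dims, " ")[[1]]),
                dx = as.numeric(h$dx),
                inside = d$inside == 1L, region = d$region,
                fibre = if (h$has_fibre == "1") fib else NULL,
                d_iso = as.numeric(h$d_iso), d_long = as.numeric(h$d_long),
                d_trans = as.numeric(h$d_trans),
                periodic = h$periodic == "1")
}

#' Run a declared experiment from a configuration file
#'
#' Executes one of the package's standard experiments from a single YAML
#' config and writes its artefacts next to the config (or under `out_dir`).
#' Supported `experiment` values: `"cell_pace"` (trace CSV + metrics),
#' `"restitution"`, `"erp_cell"`, `"cv"` (cable conduction velocity).
#' The physics is fully deterministic, so identical configs give
#' bit-identical outputs; every metrics file records the package version
#' and the config hash.
#'
#' @param path path to a YAML configuration.
#' @param out_dir output directory (default: directory of `path`).
#' @return Named list of artefact paths, invisibly.
#' @export
run_config <- function(path, out_dir = dirname(path)) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("config parse error: ",
                                           conditionMessage(e)))
  need <- function(key) {
    if (is.null(cfg[[key]])) stop("config error: missing '", key, "'")
    cfg[[key]]
  }
  exp_type <- need("experiment")
  region <- if (is.null(cfg$region)) "RA" else cfg$region
  af <- if (is.null(cfg$af)) "CONTROL" else cfg$af
  if (!af %in% c("CONTROL", "AF0", "AF1", "AF2", "AF3", "AF4"))
    stop("config error: unknown AF scenario '", af, "'")
  if (!region %in% region_ids())
    stop("config error: unknown region '", region, "'")
  params <- apply_af(apply_region(channel_params(), region), af)
  stem <- file.path(out_dir, sub("\\.[yY][aA]?[mM][lL]$", "",
                                 basename(path)))
  cfg_hash <- sprintf("%08x",
                      sum(utf8ToInt(paste(readLines(path), collapse = "\n")) *
                          seq_along(utf8ToInt(paste(readLines(path),
                                                    collapse = "\n")))) %%
                      .Machine$integer.max)
  meta <- c(paste("package_version =", as.character(utils::packageVersion("atriasim"))),
            paste("config_hash =", cfg_hash),
            paste("experiment =", exp_type))
  out <- list()
  if (exp_type == "cell_pace") {
    bcl <- if (is.null(cfg$bcl)) 1000 else cfg$bcl
    nb <- if (is.null(cfg$n_beats)) 10 else cfg$n_beats
    tr <- pace_cell(params, bcl = bcl, n_beats = nb)
    out$trace <- write_trace(tr, paste0(stem, "_trace.csv"))
    m <- cat_metrics(tr)
    writeLines(c(meta,
                 paste("apd90_ms =", format(measure_apd(tr), digits = 10)),
                 paste("cat_amplitude_mM =", format(m$amplitude, digits = 10)),
                 paste("cat_diastolic_mM =", format(m$diastolic, digits = 10))),
               out$metrics <- paste0(stem, "_metrics.txt"))
  } else if (exp_type == "restitution") {
    bcls <- if (is.null(cfg$bcl_list)) c(1000, 800, 600, 500, 400, 350, 300)
            else as.numeric(cfg$bcl_list)
    rc <- restitution(params, bcls)
    utils::write.csv(data.frame(bcl = rc$bcl, di = rc$di, apd90 = rc$apd90),
                     out$curve <- paste0(stem, "_restitution.csv"),
                     row.names = FALSE)
    writeLines(c(meta, paste("max_slope =", format(rc$max_slope, digits = 10))),
               out$metrics <- paste0(stem, "_metrics.txt"))
  } else if (exp_type == "erp_cell") {
    erp <- measure_erp_cell(params)
    writeLines(c(meta, paste("erp_ms =", erp)),
               out$metrics <- paste0(stem, "_metrics.txt"))
  } else if (exp_type == "cv") {
    nn <- if (is.null(cfg$n_nodes)) 200 else cfg$n_nodes
    geom <- make_cable(nn, region_layout =
                         stats::setNames(list(seq_len(nn)), region))
    cv <- measure_cv(geom, af)
    writeLines(c(meta, paste("cv_m_per_s =", format(cv$cv, digits = 10)),
                 paste("blocked =", as.integer(cv$blocked))),
               out$metrics <- paste0(stem, "_metrics.txt"))
  } else {
    stop("config error: unknown experiment '", exp_type, "'")
  }
  invisible(out)
}
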