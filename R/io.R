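# Snapshot I/O. Geometry goes into a single OFF polygon-mesh file (apical
# vertices and faces first, then the basal block, readable by standard mesh
# viewers); everything else (time, per-junction tensions, model parameters,
# RNG state) goes into a YAML sidecar next to it. Positions are printed with
# 17 significant digits, so a write/read round-trip is bit-exact and a saved
# run can be resumed reproducibly.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a shell mesh to an OFF file with a YAML sidecar
#'
#' @param mesh a `shell_mesh`.
#' @param path output path (conventionally `.off`); the sidecar is written
#'   to `paste0(path, ".yaml")`.
#' @param params optional `model_params` stored in the sidecar.
#' @param extra optional named list of extra state (e.g. per-cell volume
#'   targets) stored in the sidecar.
#' @param rng_state optional RNG state (`.Random.seed`) to store.
#' @return `path`, invisibly.
#' @export
write_shell <- function(mesh, path, params = NULL, extra = list(),
                        rng_state = NULL) {
  nv <- nrow(mesh$apical)
  nc <- length(mesh$cells)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", 2 * nv, 2 * nc), con)
  pos <- rbind(mesh$apical, mesh$basal)
  writeLines(paste(fmt_num(pos[, 1]), fmt_num(pos[, 2]), fmt_num(pos[, 3])),
             con)
  face_line <- function(ids) paste(c(length(ids), ids - 1L), collapse = " ")
  writeLines(vapply(mesh$cells, face_line, character(1)), con)
  writeLines(vapply(mesh$cells, function(f) face_line(f + nv), character(1)),
             con)
  # numeric state is serialised as %.17g strings: always bit-exact on re-read
  meta <- list(format = "epivertex-shell", version = 1L,
               n_apical_vertices = nv, n_cells = nc, time = fmt_num(mesh$time),
               gamma = fmt_num(as.numeric(mesh$gamma)))
  if (!is.null(params))
    meta$params <- lapply(unclass(params), fmt_num)
  if (length(extra) > 0) meta$extra <- extra
  if (!is.null(rng_state)) meta$rng_state <- as.integer(rng_state)
  yaml::write_yaml(meta, paste0(path, ".yaml"), precision = 17)
  invisible(path)
}

#' Read a shell mesh written by [write_shell()]
#'
#' @param path the OFF file path.
#' @return a list with `mesh` and, when present in the sidecar, `params`,
#'   `extra`, and `rng_state`.
#' @export
read_shell <- function(path) {
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path))
    stop("missing sidecar metadata file: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  if (!identical(meta$format, "epivertex-shell"))
    stop("not an epivertex shell snapshot: ", path)
  if (!identical(as.integer(meta$version), 1L))
    stop("unsupported snapshot version: ", meta$version)
  lines <- readLines(path)
  stopifnot(lines[1] == "OFF")
  counts <- scan(text = lines[2], quiet = TRUE)
  nvt <- counts[1]
  nv <- meta$n_apical_vertices
  nc <- meta$n_cells
  stopifnot(nvt == 2 * nv)
  pos <- matrix(scan(text = lines[3:(2 + nvt)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  cells <- lapply(lines[(3 + nvt):(2 + nvt + nc)], function(l) {
    v <- scan(text = l, quiet = TRUE)
    as.integer(v[-1] + 1L)
  })
  mesh <- shell_mesh(pos[seq_len(nv), , drop = FALSE],
                     pos[nv + seq_len(nv), , drop = FALSE], cells,
                     gamma = as.numeric(unlist(meta$gamma)),
                     time = as.numeric(meta$time))
  out <- list(mesh = mesh)
  if (!is.null(meta$params)) {
    p <- lapply(meta$params, as.numeric)
    out$params <- do.call(model_params,
                          p[names(p) %in% names(formals(model_params))])
  }
  if (!is.null(meta$extra)) {
    out$extra <- meta$extra
    if (!is.null(meta$extra$protocol_state))
      out$state <- decode_state(meta$extra$protocol_state)
  }
  if (!is.null(meta$rng_state)) out$rng_state <- as.integer(meta$rng_state)
  out
}

#' Save a resumable simulation snapshot
#'
#' Stores the mesh, parameters, auxiliary state, and the current RNG state,
#' so that a run continued from the snapshot reproduces the uninterrupted
#' trajectory bit for bit (see [restore_rng()]).
#'
#' @param mesh a `shell_mesh`.
#' @param path output path.
#' @param params a `model_params`.
#' @param state protocol state from a `shell_trajectory` (`$state`): open
#'   rosette dwells, refractory junctions, volume targets, growth phases.
#' @param extra named list of further sidecar entries.
#' @return `path`, invisibly.
#' @export
save_snapshot <- function(mesh, path, params = NULL, state = NULL,
                          extra = list()) {
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  if (!is.null(state)) extra$protocol_state <- encode_state(state)
  write_shell(mesh, path, params = params, extra = extra, rng_state = rng)
}

encode_state <- function(state) {
  list(dwells = lapply(state$dwells, function(d)
    list(u = d$u, v = d$v, resolve_step = d$resolve_step,
         e_dir = fmt_num(d$e_dir), cells = as.integer(d$cells))),
    refr_keys = as.list(state$refr_keys),
    vt = fmt_num(state$vt), phase = as.integer(state$phase))
}

decode_state <- function(x) {
  list(dwells = lapply(x$dwells, function(d)
    list(u = as.integer(d$u), v = as.integer(d$v),
         resolve_step = as.numeric(d$resolve_step),
         e_dir = as.numeric(unlist(d$e_dir)),
         cells = as.integer(unlist(d$cells)))),
    refr_keys = as.character(unlist(x$refr_keys)),
    vt = as.numeric(unlist(x$vt)), phase = as.integer(unlist(x$phase)))
}

#' Restore the RNG state from a loaded snapshot
#'
#' @param snapshot result of [read_shell()].
#' @return `TRUE` invisibly if a state was restored.
#' @export
restore_rng <- function(snapshot) {
  if (is.null(snapshot$rng_state)) return(invisible(FALSE))
  assign(".Random.seed", as.integer(snapshot$rng_state), envir = globalenv())
  invisible(TRUE)
}

#' Write a trajectory's event and energy logs as CSV
#'
#' @param trajectory a `shell_trajectory`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_trajectory_logs <- function(trajectory, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(trajectory$energy, file.path(dir, "energy.csv"),
            row.names = FALSE)
  write.csv(trajectory$events, file.path(dir, "events.csv"),
            row.names = FALSE)
  invisible(dir)
}
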