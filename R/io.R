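#' Write a trajectory as CSV
#'
#' Columns `t,x1,y1,z,x2,y2,u` for the Epileptor (or `t,x,y,z` / `t,x,y`
#' for the DTB models), '.' decimal, LF endings, no index column.
#'
#' @param traj a `dyn_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "dyn_trajectory"))
  df <- as.data.frame(traj)
  names(df)[1] <- "t"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' The model tag is inferred from the header.
#'
#' @param path CSV file path.
#' @return A `dyn_trajectory` (without parameter attributes).
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  names(df)[1] <- "time"
  model <- if (all(c("x1", "u") %in% names(df))) "epileptor"
           else if ("z" %in% names(df)) "dtb" else "fast"
  class(df) <- c("dyn_trajectory", "data.frame")
  attr(df, "model") <- model
  df
}

#' Export the analytic bifurcation curves as CSV polylines
#'
#' One CSV `curves.csv` with columns `mbar,mu,curve_label` (labels `SN-`,
#' `SN+`, `SN0`, `Hopf`, and `SH` when attached) sampled over
#' `mbar_range`, plus `tb_point.json` holding the Takens-Bogdanov point.
#'
#' @param bs a [bifurcation_set()].
#' @param dir output directory (created if needed).
#' @param mbar_range,n sampling range and density for the curved/valid
#'   segments.
#' @return Character vector of files written, invisibly.
#' @export
write_bifurcation_set <- function(bs, dir, mbar_range = c(-3, 2), n = 121) {
  stopifnot(inherits(bs, "bifurcation_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mb <- seq(mbar_range[1], mbar_range[2], length.out = n)
  rows <- list(
    data.frame(mbar = mb, mu = bs$sn$sn_minus$mu, curve_label = "SN-"),
    data.frame(mbar = mb[bs$sn$sn_plus$mbar_valid(mb)],
               mu = bs$sn$sn_plus$mu_of_mbar(mb[bs$sn$sn_plus$mbar_valid(mb)]),
               curve_label = "SN+"),
    data.frame(mbar = mb[mb <= bs$sn$sn_zero$mbar_max],
               mu = bs$sn$sn_zero$mu, curve_label = "SN0"),
    data.frame(mbar = bs$hopf$mbar,
               mu = seq(bs$hopf$mu_min, max(mbar_range[2], bs$hopf$mu_min + 1),
                        length.out = n),
               curve_label = "Hopf"))
  if (!is.null(bs$sh) && nrow(bs$sh))
    rows <- c(rows, list(data.frame(mbar = bs$sh$mbar, mu = bs$sh$mu,
                                    curve_label = "SH")))
  curves <- do.call(rbind, rows)
  f1 <- file.path(dir, "curves.csv")
  utils::write.csv(curves, f1, row.names = FALSE, quote = FALSE, eol = "\n")
  f2 <- file.path(dir, "tb_point.json")
  jsonlite::write_json(as.list(bs$tb), f2, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2))
}

#' Export fixed points as CSV
#'
#' Columns `mu,mbar,x,y,branch,stability`.
#'
#' @param fp a [fast_params()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fixed_points <- function(fp, path) {
  pts <- fixed_points(fp)
  df <- cbind(mu = fp$mu, mbar = fp$mbar, pts[c("x", "y", "branch",
                                                "stability")])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Export a simulated map grid as CSV matrices
#'
#' Writes `axes.csv` (long table of the two axes), plus `amplitude.csv`,
#' `frequency.csv` and `converged.csv` matrices (rows = `mu` values,
#' columns = `mbar` values).
#'
#' @param grid a `map_grid`.
#' @param dir output directory.
#' @return Character vector of files written, invisibly.
#' @export
write_map_grid <- function(grid, dir) {
  stopifnot(inherits(grid, "map_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  axes <- data.frame(
    axis = rep(c("mu", "mbar"), c(length(grid$mu_values),
                                  length(grid$mbar_values))),
    value = c(grid$mu_values, grid$mbar_values))
  f <- file.path(dir, "axes.csv")
  utils::write.csv(axes, f, row.names = FALSE, quote = FALSE, eol = "\n")
  files <- f
  for (nm in c("amplitude", "frequency", "converged_to_fp")) {
    f <- file.path(dir, paste0(sub("_to_fp", "", nm), ".csv"))
    utils::write.table(grid[[nm]], f, row.names = FALSE, col.names = FALSE,
                       sep = ",", eol = "\n")
    files <- c(files, f)
  }
  invisible(files)
}

#' Load a configuration file
#'
#' YAML key/value configuration: top-level keys are Epileptor parameters
#' (overlaid on the model defaults), with one optional nesting level
#' `solver:` for [solve_options()] arguments. Unknown keys are rejected
#' with the list of valid keys; type mismatches are rejected.
#'
#' @param path YAML file path.
#' @return List with `params` ([epileptor_params()]) and `opts`
#'   ([solve_options()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  solver <- cfg$solver
  cfg$solver <- NULL
  pkeys <- names(formals(epileptor_params))
  bad <- setdiff(names(cfg), pkeys)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(pkeys, collapse = ", "))
  if (!all(vapply(cfg, function(v) is.numeric(v) && length(v) == 1, TRUE)))
    stop("config values must be single numbers")
  skeys <- names(formals(solve_options))
  bads <- setdiff(names(solver), skeys)
  if (length(bads))
    stop("unknown solver key(s): ", paste(bads, collapse = ", "),
         "; valid keys: ", paste(skeys, collapse = ", "))
  list(params = do.call(epileptor_params, cfg),
       opts = do.call(solve_options, if (is.null(solver)) list() else solver))
}

#' Serialize a parameter object to YAML
#'
#' Round-trips through [load_config()] losslessly.
#'
#' @param params an [epileptor_params()] object.
#' @param path output YAML path.
#' @param opts optional [solve_options()] written under the `solver:` key.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, opts = NULL) {
  stopifnot(inherits(params, "epileptor_params"))
  cfg <- unclass(params)
  if (!is.null(opts)) cfg$solver <- unclass(opts)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a set of result objects with a manifest
#'
#' Dispatches on object class (`dyn_trajectory`, `bifurcation_set`,
#' `map_grid`, `burster_classification`) and writes a `manifest.csv`
#' listing every file with its MD5 checksum.
#'
#' @param objects named list of objects.
#' @param out_dir output directory.
#' @return Data frame manifest (file, md5), invisibly.
#' @export
write_outputs <- function(objects, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(objects)) {
    ob <- objects[[nm]]
    files <- c(files, if (inherits(ob, "dyn_trajectory")) {
      write_trajectory(ob, file.path(out_dir, paste0(nm, ".csv")))
    } else if (inherits(ob, "bifurcation_set")) {
      write_bifurcation_set(ob, file.path(out_dir, nm))
    } else if (inherits(ob, "map_grid")) {
      write_map_grid(ob, file.path(out_dir, nm))
    } else if (inherits(ob, "burster_classification")) {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(list(label = ob$label,
                                onset_type = ob$onset_type,
                                offset_type = ob$offset_type,
                                diagnostics = ob$diagnostics,
                                events = ob$events),
                           f, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      f
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(ob, f, auto_unbox = TRUE, digits = NA)
      f
    })
  }
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(manifest)
}
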