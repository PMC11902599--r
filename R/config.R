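# Pipeline configuration: defaults, YAML round-trip, key=value overrides.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the reconstruction.  The defaults
#' are the reference acquisition's operating point: match ratio 0.6, 5
#' randomized kd-trees in 1 ANN index, disease threshold 110 counts,
#' reprojection scale `s = 0.02`, upsampling factor 5, matching on the ExG
#' channel, and the 1440x1080 camera with 3.45 um pixels behind an 8 mm
#' objective.
#'
#' @param ... Named overrides of any default (unknown names are an error).
#' @return A `recon_config` list.
#' @export
recon_config <- function(...) {
  cfg <- list(
    intrinsics = list(f = 8, ku = 1 / 0.00345, kv = 1 / 0.00345,
                      u0 = 720, v0 = 540, s = 0.02),
    upsample_factor = 5L,
    match_ratio = 0.6,
    ann = list(kdtree = 1L, trees = 5L, checks = 128L),
    match_method = "kdtree",
    max_vertical_drift = 20,
    disease_threshold = 110,
    channel_for_matching = "exg",
    world_scale = 1,
    mask_min_exg = 5,
    mask_smooth_sigma = 1,
    densify = TRUE,
    densify_method = "linear",
    nfeatures = 0L,
    double_image = TRUE,
    ransac = FALSE,
    ransac_tol = 3,
    seed = 1234L)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    for (nm in names(over)) {
      cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
        modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
    }
  }
  validate_config(structure(cfg, class = "recon_config"))
}

validate_config <- function(cfg) {
  stopifnot(cfg$match_ratio > 0, cfg$match_ratio <= 1,
            cfg$upsample_factor >= 1,
            cfg$max_vertical_drift >= 0,
            cfg$disease_threshold >= 0,
            cfg$world_scale > 0,
            cfg$ann$trees >= 1, cfg$ann$checks >= 1)
  cfg$channel_for_matching <- match.arg(cfg$channel_for_matching,
                                        c("exg", "gray", "red", "green", "blue"))
  cfg$match_method <- match.arg(cfg$match_method, c("kdtree", "exact"))
  cfg$densify_method <- match.arg(cfg$densify_method, c("linear", "nearest"))
  # intrinsics validated by construction
  as_intrinsics(cfg)
  cfg
}

#' Camera intrinsics stored in a config
#' @param cfg A `recon_config`.
#' @export
as_intrinsics <- function(cfg) {
  with(cfg$intrinsics,
       camera_intrinsics(f = f, ku = ku, kv = kv, u0 = u0, v0 = v0, s = s))
}

#' @export
print.recon_config <- function(x, ...) {
  cat("<recon_config>\n")
  cat(sprintf("  channel %s, upsample x%d, ratio %g, drift %g px, tau %g\n",
              x$channel_for_matching, x$upsample_factor, x$match_ratio,
              x$max_vertical_drift, x$disease_threshold))
  cat(sprintf("  intrinsics: f=%g ku=%.4g u0=%g v0=%g s=%g\n",
              x$intrinsics$f, x$intrinsics$ku, x$intrinsics$u0,
              x$intrinsics$v0, x$intrinsics$s))
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults of [recon_config()].
#'
#' @param path YAML file.
#' @export
read_config <- function(path) {
  do.call(recon_config, yaml::read_yaml(path))
}

#' Write a resolved configuration to YAML (provenance copy)
#'
#' @param cfg A `recon_config`.
#' @param path Output file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Apply `key=value` overrides to a configuration
#'
#' Dotted keys address nested fields (`intrinsics.s=0.02`); values are
#' parsed as YAML scalars.
#'
#' @param cfg A `recon_config`.
#' @param sets Character vector of `key=value` strings.
#' @export
config_set <- function(cfg, sets) {
  for (kv in sets) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) stop("override must look like key=value: ", kv)
    key <- strsplit(substr(kv, 1, eq - 1), ".", fixed = TRUE)[[1]]
    val <- yaml::yaml.load(substr(kv, eq + 1, nchar(kv)))
    if (length(key) == 1) cfg[[key]] <- val
    else if (length(key) == 2) cfg[[key[1]]][[key[2]]] <- val
    else stop("override key too deep: ", kv)
  }
  validate_config(cfg)
}
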