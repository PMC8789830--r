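# File I/O: multi-page 16-bit TIFF volumes (pages are depth slices, rows
# the x fast axis, columns the y slow axis; 0-based indices documented in
# the side-car YAML), PNG/TIFF enface images, YAML configs and CSV pair
# manifests. Values are stored as 16-bit integers with linear [0,1]
# scaling, a lossless round trip up to 1/65535 quantization.

#' Write a volume as a multi-page 16-bit TIFF
#'
#' @param vol an `octra_angiogram` or a 3-d `(X, Y, Z)` array in `[0, 1]`;
#'   pages are depth slices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vals <- if (inherits(vol, "octra_angiogram")) vol$values else vol
  stopifnot(length(dim(vals)) == 3L, min(vals) >= 0, max(vals) <= 1)
  pages <- lapply(seq_len(dim(vals)[3]), function(z) vals[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF volume
#'
#' @param path file path.
#' @param expected_pages if given, the file must contain exactly this many
#'   depth pages (e.g. the declared Z extent).
#' @return A 3-d `(X, Y, Z)` array in `[0, 1]`.
#' @export
read_volume <- function(path, expected_pages = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!is.null(expected_pages) && length(pages) != expected_pages) {
    stop("file ", path, " has ", length(pages), " pages; expected ",
         expected_pages, " depth slices (layout: pages = z, rows = x, ",
         "cols = y)")
  }
  d <- dim(pages[[1]])
  out <- array(0, dim = c(d[1], d[2], length(pages)))
  for (z in seq_along(pages)) out[, , z] <- pages[[z]]
  out
}

#' Write a repeated-frame phantom series to a directory
#'
#' One multi-page TIFF per repeat (`repeat_01.tif`, ...), the vessel mask
#' as `vessel_mask.tif` (0/1 pages) and the phantom spec as `spec.yaml`
#' (including the axis convention).
#'
#' @param series an `octra_series`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "octra_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  R <- dim(series$frames)[1]
  for (r in seq_len(R)) {
    write_volume(series$frames[r, , , ], file.path(dir,
                 sprintf("repeat_%02d.tif", r)))
  }
  write_volume(series$vessel_mask * 1, file.path(dir, "vessel_mask.tif"))
  spec <- series$spec
  yaml::write_yaml(list(
    axis_order = "pages = z (depth), rows = x (fast), cols = y (slow); 0-based",
    n_repeats = R,
    grid_size = as.integer(spec$grid_size),
    n_vessels = spec$n_vessels,
    radius_range = spec$radius_range,
    flow_decorrelation = spec$flow_decorrelation,
    static_noise_sigma = spec$static_noise_sigma,
    seed = spec$seed
  ), file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' Read a phantom series written by [write_series()]
#'
#' @param dir directory containing `repeat_*.tif`, `vessel_mask.tif` and
#'   `spec.yaml`.
#' @return An `octra_series`.
#' @export
read_series <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "spec.yaml"))
  gs <- as.integer(meta$grid_size)
  R <- meta$n_repeats
  frames <- array(0, dim = c(R, gs))
  for (r in seq_len(R)) {
    frames[r, , , ] <- read_volume(file.path(dir,
                                   sprintf("repeat_%02d.tif", r)),
                                   expected_pages = gs[3])
  }
  mask <- read_volume(file.path(dir, "vessel_mask.tif"),
                      expected_pages = gs[3]) > 0.5
  spec <- phantom_spec(grid_size = gs, n_vessels = meta$n_vessels,
                       radius_range = as.numeric(meta$radius_range),
                       flow_decorrelation = meta$flow_decorrelation,
                       static_noise_sigma = meta$static_noise_sigma,
                       seed = meta$seed)
  structure(list(frames = frames, vessel_mask = mask, spec = spec),
            class = "octra_series")
}

#' Write an enface image as a 16-bit TIFF
#'
#' @param img an [enface_image()] or matrix in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enface <- function(img, path) {
  px <- as_pixels(img)
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an enface image from TIFF
#'
#' @param path file path.
#' @param kind,depth_index metadata for the returned [enface_image()].
#' @return An [enface_image()].
#' @export
read_enface <- function(path, kind = "sectioned", depth_index = NULL) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  enface_image(px, kind, depth_index)
}

#' Write a paired-sample manifest (images + CSV)
#'
#' Each pair's three images are written as 16-bit TIFFs under `dir` and
#' indexed by `manifest.csv` with columns `id`, `lr_lq`, `hr_lq`,
#' `hr_hq`, `ratio`, `split`.
#'
#' @param pairs list of `octra_pair` objects.
#' @param dir output directory.
#' @param split character vector of split labels (recycled).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_pairs_manifest <- function(pairs, dir, split = "train") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  split <- rep_len(split, length(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    files <- c(lr_lq = sprintf("pair%04d_lr_lq.tif", i),
               hr_lq = sprintf("pair%04d_hr_lq.tif", i),
               hr_hq = sprintf("pair%04d_hr_hq.tif", i))
    for (f in names(files)) write_enface(p[[f]], file.path(dir, files[f]))
    data.frame(id = i - 1L, lr_lq = files["lr_lq"], hr_lq = files["hr_lq"],
               hr_hq = files["hr_hq"], ratio = p$ratio, split = split[i])
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a paired-sample manifest
#'
#' @param dir directory written by [write_pairs_manifest()].
#' @param split optional split label filter.
#' @return List of `octra_pair` objects.
#' @export
read_pairs_manifest <- function(dir, split = NULL) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, ]
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    structure(list(
      lr_lq = read_enface(file.path(dir, row$lr_lq)),
      hr_lq = read_enface(file.path(dir, row$hr_lq)),
      hr_hq = read_enface(file.path(dir, row$hr_hq)),
      ratio = as.integer(row$ratio),
      depth_index = NULL
    ), class = "octra_pair")
  })
}

#' Save / load generator weights
#'
#' Checkpoints are plain YAML: the network config plus every parameter
#' flattened to a numeric vector (text-only, portable).
#'
#' @param G an `octra_generator`.
#' @param path output YAML path.
#' @return `path` invisibly; `load_generator()` returns the generator.
#' @export
save_generator <- function(G, path) {
  params <- unname(c(collect_params(G$sr), collect_params(G$qe)))
  yaml::write_yaml(list(
    config = unclass(G$config),
    params = lapply(params, function(p) {
      list(dim = as.integer(if (is.null(dim(p$value))) length(p$value)
                            else dim(p$value)),
           data = as.numeric(p$value))
    })
  ), path, precision = 17L)
  invisible(path)
}

#' @rdname save_generator
#' @param path YAML checkpoint path.
#' @export
load_generator <- function(path) {
  ck <- yaml::read_yaml(path)
  cfg <- do.call(net_config, ck$config)
  G <- build_generator(cfg, seed = 1L)
  params <- c(collect_params(G$sr), collect_params(G$qe))
  stopifnot(length(params) == length(ck$params))
  for (i in seq_along(params)) {
    v <- as.numeric(ck$params[[i]]$data)
    d <- as.integer(ck$params[[i]]$dim)
    if (length(d) > 1L) dim(v) <- d
    params[[i]]$value <- v
  }
  G$trained <- TRUE
  G
}
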