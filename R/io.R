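#' Read a grayscale image or volume
#'
#' Supported formats, chosen by extension: PNG rasters (8- or 16-bit,
#' decoded to \[0, 1\] floats), TIFF rasters (8/16-bit, same scaling;
#' multi-channel rasters are averaged to grayscale), NIfTI volumes (`.nii` / `.nii.gz`, float intensities, voxel
#' spacing taken from the header `pixdim`, falling back to 1 mm with a
#' warning when the header carries none), and plain numeric arrays
#' (`.txt` / `.csv`, whitespace- or comma-separated matrix of numbers).
#' Raster spacing defaults to 1 mm per axis.
#'
#' @param path file path.
#' @param modality modality tag to attach (default taken from the format).
#' @return An [image_grid].
#' @export
read_image <- function(path, modality = NULL) {
  if (!file.exists(path)) {
    stop("cannot read '", path, "': no such file", call. = FALSE)
  }
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) ext <- "nii"
  vals <- spacing <- NULL
  tag <- modality
  if (ext == "png") {
    vals <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    vals <- tiff::readTIFF(path)
  } else if (ext == "nii") {
    img <- RNifti::readNifti(path)
    vals <- as.array(img)
    pd <- RNifti::pixdim(img)
    nd <- length(dim(vals))
    if (length(pd) >= nd && all(pd[seq_len(nd)] > 0)) {
      spacing <- pd[seq_len(nd)]
    } else {
      warning("'", path, "': no usable voxel spacing in header; using 1 mm",
              call. = FALSE)
    }
    if (is.null(tag)) tag <- "NIfTI"
  } else if (ext %in% c("txt", "csv")) {
    vals <- as.matrix(utils::read.table(path, header = FALSE,
                                        sep = if (ext == "csv") "," else ""))
    dimnames(vals) <- NULL
  } else {
    stop("unsupported image format '.", ext, "' for '", path, "'", call. = FALSE)
  }
  if (length(dim(vals)) == 3L && ext %in% c("png", "tif", "tiff")) {
    vals <- apply(vals, c(1, 2), mean)    # collapse channels to grayscale
  }
  if (is.null(tag)) tag <- toupper(ext)
  image_grid(vals, spacing = spacing, modality = tag)
}

#' Write a grayscale image or volume
#'
#' Format chosen by extension: PNG is written as an 8-bit raster and TIFF
#' as a 16-bit raster; both require intensities in \[0, 1\] unless
#' `rescale = TRUE` (which maps the observed range onto \[0, 1\]).  NIfTI
#' is written as float with the grid's voxel spacing (lossless to float
#' precision); `.txt`/`.csv` write a plain numeric matrix.
#'
#' @param grid an [image_grid].
#' @param path output path; the parent directory must exist.
#' @param rescale rescale out-of-range raster intensities instead of
#'   raising an error.
#' @return Invisibly, `path`.
#' @export
write_image <- function(grid, path, rescale = FALSE) {
  stopifnot(is_image_grid(grid))
  if (!dir.exists(dirname(path))) {
    stop("parent directory of '", path, "' does not exist", call. = FALSE)
  }
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) ext <- "nii"
  v <- grid$values
  if (ext %in% c("png", "tif", "tiff")) {
    if (length(dim(v)) != 2L) {
      stop("raster formats hold 2-D images; use NIfTI for volumes", call. = FALSE)
    }
    if (min(v) < 0 || max(v) > 1) {
      if (!rescale) {
        stop("intensities outside [0, 1]; pass rescale = TRUE or use NIfTI",
             call. = FALSE)
      }
      rng <- range(v)
      v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
    }
    if (ext == "png") png::writePNG(v, path, dpi = NULL) else
      tiff::writeTIFF(v, path, bits.per.sample = 16L)
  } else if (ext == "nii") {
    img <- RNifti::asNifti(v)
    RNifti::pixdim(img) <- grid$spacing
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (ext %in% c("txt", "csv")) {
    utils::write.table(v, path, row.names = FALSE, col.names = FALSE,
                       sep = if (ext == "csv") "," else " ")
  } else {
    stop("unsupported image format '.", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Derive a named per-stage RNG seed
#'
#' All randomness in a pipeline run flows from one config seed; each stage
#' draws from its own substream whose seed is a deterministic hash of the
#' master seed and the stage name, kept below 2^31.
#'
#' @param seed master integer seed.
#' @param name stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, name) {
  h <- 0
  for (b in utf8ToInt(as.character(name))) h <- (h * 31 + b) %% 2147480009
  as.integer(((seed %% 1000003) * 7919 + h) %% 2147483629)
}

#' Run the simulate / denoise / evaluate / segment pipeline
#'
#' Executes the full image-optimization chain on a synthetic phantom:
#' \enumerate{
#'   \item \strong{simulate} — build a phantom ([make_phantom()]) and
#'     corrupt it with multiplicative Rayleigh speckle
#'     ([apply_speckle()]);
#'   \item \strong{denoise} — homomorphic MAP denoising
#'     ([denoise_image()]);
#'   \item \strong{evaluate} — SNR/SSIM of noisy and denoised images
#'     against the clean phantom ([quality_report()]);
#'   \item \strong{segment} — best-threshold segmentation and edge
#'     detection of the denoised image ([best_threshold_segment()],
#'     [edge_detect()]).
#' }
#' Images are written as float NIfTI, the mask as run-length-encoded CSV,
#' and a manifest JSON records the package version, seeds, parameters and
#' per-stage status.  Identical config and seed give identical artifacts
#' (the manifest timestamp aside).
#'
#' @param config a named list (or path to a JSON file) with elements:
#'   `seed` (integer), `outdir` (output directory, created if needed),
#'   `simulate` (list: `shape`, `kind`, `d`, `additive_sigma`),
#'   `denoise` (list passed to [map_config()]; `use_speckle_model = TRUE`
#'   forwards the simulated `d` as `speckle_d`), and `segment`
#'   (list: `levels`).  Missing elements take the defaults of the
#'   underlying functions.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("`config` must be a list or a JSON path", call. = FALSE)
  known <- c("seed", "outdir", "simulate", "denoise", "evaluate", "segment")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  seed <- as.integer(config$seed %||% 0L)
  outdir <- config$outdir %||% stop("config needs an `outdir`", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  manifest <- list(
    package = "speckleMAP",
    version = as.character(utils::packageVersion("speckleMAP")),
    seed = seed, config = config, timestamp = format(Sys.time()),
    stages = list()
  )

  sim <- config$simulate %||% list()
  shape <- unlist(sim$shape %||% c(64L, 64L))
  kind <- sim$kind %||% "blobs"
  d <- sim$d %||% 0.5
  add_sigma <- sim$additive_sigma %||% 0
  st <- run_stage("simulate", function() {
    clean <- make_phantom(shape, kind, seed = stage_seed(seed, "phantom"))
    par <- speckle_params(d, add_sigma, seed = stage_seed(seed, "speckle"))
    noisy <- apply_speckle(clean, par)
    cp <- file.path(outdir, "clean.nii")
    np <- file.path(outdir, "noisy.nii")
    write_image(clean, cp)
    write_image(noisy, np)
    list(status = "ok", outputs = c(clean = cp, noisy = np),
         params = list(kind = kind, shape = shape, d = d,
                       additive_sigma = add_sigma),
         clean = clean, noisy = noisy)
  })
  manifest$stages$simulate <- st[c("status", "outputs", "params")]

  dn <- config$denoise %||% list()
  use_model <- isTRUE(dn$use_speckle_model %||% TRUE)
  dn$use_speckle_model <- NULL
  if (use_model && is.null(dn$speckle_d)) dn$speckle_d <- d
  st2 <- run_stage("denoise", function() {
    cfg <- do.call(map_config, dn)
    rep <- denoise_image(st$noisy, cfg)
    dp <- file.path(outdir, "denoised.nii")
    write_image(rep$denoised, dp)
    list(status = "ok", outputs = c(denoised = dp),
         params = list(noise_d_used = rep$noise_d_used,
                       prior_d_used = rep$prior_d_used,
                       gain_removed = rep$gain_removed,
                       pixels_floored = rep$pixels_floored),
         report = rep)
  })
  manifest$stages$denoise <- st2[c("status", "outputs", "params")]

  st3 <- run_stage("evaluate", function() {
    before <- quality_report(st$clean, st$noisy)
    after <- quality_report(st$clean, st2$report$denoised)
    list(status = "ok",
         metrics = list(snr_before_db = before$snr_db, snr_after_db = after$snr_db,
                        ssim_before = before$ssim, ssim_after = after$ssim,
                        snr_gain_db = after$snr_db - before$snr_db,
                        ssim_gain = after$ssim - before$ssim))
  })
  manifest$stages$evaluate <- st3[c("status", "metrics")]

  seg <- config$segment %||% list()
  st4 <- run_stage("segment", function() {
    res <- best_threshold_segment(st2$report$denoised,
                                  levels = seg$levels %||% 256L)
    edges <- edge_detect(st2$report$denoised)
    mp <- file.path(outdir, "mask_rle.csv")
    ep <- file.path(outdir, "edges_rle.csv")
    utils::write.csv(encode_mask_rle(res$mask), mp, row.names = FALSE)
    utils::write.csv(encode_mask_rle(edges), ep, row.names = FALSE)
    list(status = "ok", outputs = c(mask = mp, edges = ep),
         params = list(threshold = res$threshold,
                       criterion_value = res$criterion_value,
                       edge_threshold = attr(edges, "threshold")))
  })
  manifest$stages$segment <- st4[c("status", "outputs", "params")]

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
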