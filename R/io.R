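# Plain-text readers/writers shared by all modules.
#
# Two image containers:
#   * "txt"  -- full-precision numeric matrix, one row per line, values
#               printed with %.17g so a write/read round trip is bit-exact.
#   * "pgm"  -- ASCII portable graymap (P2), 8-bit by default; a lossy but
#               universally viewable format whose quantization step is
#               round(x * maxval) / maxval.
# Datasets are a directory of per-subject image files plus a manifest CSV
# (subject_id, ct_path, xray_path, label).  Models serialize to a single
# text archive of named arrays with a JSON metadata header.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a numeric matrix as full-precision text
#'
#' One matrix row per line, space-separated `%.17g` values; round trips are
#' bit-exact.
#' @param m numeric matrix.
#' @param path file path.
#' @return `read_matrix_txt` returns the matrix.
#' @export
write_matrix_txt <- function(m, path) {
  stopifnot(is.matrix(m))
  writeLines(apply(m, 1L, function(r) paste(fmt_num(r), collapse = " ")), path)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, " ", fixed = TRUE), as.numeric))
}

#' Write / read an ASCII PGM (P2) grayscale image
#'
#' Intensities in \[0,1\] are quantized to `round(x * maxval)`; reading
#' returns values back on \[0,1\].
#' @param m numeric matrix with values in \[0,1\].
#' @param path file path.
#' @param maxval maximum gray value (255 = 8-bit, 65535 = 16-bit).
#' @return `read_pgm` returns the matrix on \[0,1\].
#' @export
write_pgm <- function(m, path, maxval = 255L) {
  stopifnot(is.matrix(m), all(m >= 0 & m <= 1))
  q <- round(m * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  writeLines(apply(q, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1L] != "P2") stop("only ASCII PGM (P2) is supported")
  vals <- scan(text = paste(lines[-1L], collapse = " "), quiet = TRUE)
  w <- vals[1L]; h <- vals[2L]; maxval <- vals[3L]
  px <- vals[-(1:3)]
  if (length(px) != w * h) stop("PGM pixel count does not match header")
  matrix(px, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write a cohort to disk
#'
#' Creates `path/` containing one image file per subject per modality and a
#' `manifest.csv` with columns subject_id, ct_path, xray_path, label.
#'
#' @param dataset list of [labeled_image_pair()] objects.
#' @param path output directory (created).
#' @param format `"txt"` (full precision, bit-exact round trip) or `"pgm"`
#'   (8-bit ASCII portable graymap).
#' @return The manifest data.frame, invisibly.
#' @export
write_dataset <- function(dataset, path, format = c("txt", "pgm")) {
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ext <- format
  writer <- if (format == "txt") write_matrix_txt else write_pgm
  rows <- lapply(dataset, function(p) {
    ctf <- sprintf("%s_ct.%s", p$subject_id, ext)
    xrf <- sprintf("%s_xray.%s", p$subject_id, ext)
    writer(p$ct_image, file.path(path, ctf))
    writer(p$xray_image, file.path(path, xrf))
    data.frame(subject_id = p$subject_id, ct_path = ctf, xray_path = xrf,
               label = p$label, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(path, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_dataset()]
#'
#' Validates labels (must be 0/1), file existence and the 28x28 shape,
#' reporting the offending subject_id.
#'
#' @param path dataset directory containing `manifest.csv`.
#' @return list of [labeled_image_pair()] objects.
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv under ", path)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    if (!row$label %in% c(0L, 1L))
      stop(sprintf("subject %s: label %s outside {0,1}", row$subject_id, row$label))
    ims <- lapply(c(row$ct_path, row$xray_path), function(f) {
      fp <- file.path(path, f)
      if (!file.exists(fp))
        stop(sprintf("subject %s: missing image file %s", row$subject_id, f))
      im <- if (grepl("\\.pgm$", f)) read_pgm(fp) else read_matrix_txt(fp)
      if (!all(dim(im) == c(28L, 28L)))
        stop(sprintf("subject %s: image %s is %dx%d, expected 28x28",
                     row$subject_id, f, nrow(im), ncol(im)))
      im
    })
    labeled_image_pair(row$subject_id, ims[[1L]], ims[[2L]], row$label)
  })
}

#' Write / read a phantom (image + JSON ground-truth sidecar)
#'
#' @param phantom a [generate_phantom()] result.
#' @param path image file path; the sidecar is `<path>.truth.json`.
#' @param format `"txt"` or `"pgm"`.
#' @return `read_phantom` returns a list `image`, `truth`.
#' @export
write_phantom <- function(phantom, path, format = c("txt", "pgm")) {
  format <- match.arg(format)
  if (format == "txt") write_matrix_txt(phantom$image, path)
  else write_pgm(phantom$image, path)
  side <- c(phantom$truth, list(pixel_size = phantom$spec$pixel_size))
  jsonlite::write_json(side, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  img <- if (grepl("\\.pgm$", path)) read_pgm(path) else read_matrix_txt(path)
  side <- paste0(path, ".truth.json")
  truth <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  list(image = img, truth = truth)
}

# ---- model serialization: named flat arrays + JSON metadata -------------

flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.numeric(v)) out[[key]] <- v
    else if (is.list(v)) out <- c(out, flatten_params(v, key))
  }
  out
}

write_array_archive <- function(arrays, meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#meta ", jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    d <- dim(a) %||% length(a)
    writeLines(paste("#array", nm, paste(d, collapse = "x")), con)
    writeLines(paste(fmt_num(as.vector(a)), collapse = " "), con)
  }
  invisible(path)
}

read_array_archive <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(sub("^#meta ", "", lines[1L]))
  heads <- grep("^#array ", lines)
  arrays <- list()
  for (i in seq_along(heads)) {
    parts <- strsplit(lines[heads[i]], " ")[[1L]]
    d <- as.integer(strsplit(parts[3L], "x")[[1L]])
    v <- as.numeric(strsplit(lines[heads[i] + 1L], " ")[[1L]])
    arrays[[parts[2L]]] <- if (length(d) > 1L) array(v, d) else v
  }
  list(meta = meta, arrays = arrays)
}

#' Save / load a trained model as a text archive
#'
#' Single-modal networks and fusion models both serialize to one
#' plain-text file: a JSON metadata line (class, architecture, seeds)
#' followed by each parameter array in `%.17g` precision, so reloading is
#' bit-exact.
#'
#' @param model a `network_params` or `fusion_model`.
#' @param path file path.
#' @return `load_model` returns the reconstructed model.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "network_params")) {
    meta <- list(class = "network_params",
                 n_classes = model$n_classes, modality_tag = model$modality_tag,
                 input_size = model$input_size, kernel_size = model$kernel_size,
                 seed = model$seed)
    arrays <- flatten_params(model[c("conv1", "conv2", "fc1", "fc2")])
  } else if (inherits(model, "fusion_model")) {
    meta <- list(class = "fusion_model", n_classes = model$n_classes,
                 spec = model$spec[c("target_dim", "seed", "scale", "combine_mode")],
                 freeze_backbones = model$freeze_backbones,
                 trainable_projections = model$trainable_projections,
                 ct = list(n_classes = model$ct_backbone$n_classes,
                           modality_tag = model$ct_backbone$modality_tag,
                           input_size = model$ct_backbone$input_size,
                           kernel_size = model$ct_backbone$kernel_size,
                           seed = model$ct_backbone$seed),
                 xray = list(n_classes = model$xray_backbone$n_classes,
                             modality_tag = model$xray_backbone$modality_tag,
                             input_size = model$xray_backbone$input_size,
                             kernel_size = model$xray_backbone$kernel_size,
                             seed = model$xray_backbone$seed))
    arrays <- c(flatten_params(model["proj"]),
                flatten_params(model[c("head_fc", "head_out")]),
                flatten_params(list(ct_backbone = model$ct_backbone[c("conv1", "conv2", "fc1", "fc2")],
                                    xray_backbone = model$xray_backbone[c("conv1", "conv2", "fc1", "fc2")])))
  } else stop("unsupported model class")
  write_array_archive(arrays, meta, path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ar <- read_array_archive(path)
  meta <- ar$meta
  if (meta$class == "network_params") {
    rebuild_network(meta, ar$arrays, "")
  } else if (meta$class == "fusion_model") {
    ct <- rebuild_network(meta$ct, ar$arrays, "ct_backbone.")
    xr <- rebuild_network(meta$xray, ar$arrays, "xray_backbone.")
    spec <- fusion_spec(meta$spec$target_dim, meta$spec$seed, meta$spec$scale,
                        meta$spec$combine_mode)
    m <- build_fusion_model(ct, xr, spec, meta$n_classes,
                            meta$freeze_backbones, meta$trainable_projections)
    for (nm in names(m$proj))
      m$proj[[nm]] <- matrix(ar$arrays[[paste0("proj.", nm)]],
                             nrow(m$proj[[nm]]), ncol(m$proj[[nm]]))
    for (h in c("head_fc", "head_out")) {
      m[[h]]$weights <- matrix(ar$arrays[[paste0(h, ".weights")]],
                               nrow(m[[h]]$weights), ncol(m[[h]]$weights))
      m[[h]]$biases <- ar$arrays[[paste0(h, ".biases")]]
    }
    m
  } else stop("unknown archive class: ", meta$class)
}

rebuild_network <- function(meta, arrays, prefix) {
  net <- build_network(meta$n_classes, meta$seed %||% 1L, meta$modality_tag,
                       meta$kernel_size, meta$input_size)
  for (layer in c("conv1", "conv2")) {
    net[[layer]]$kernels <- array(arrays[[paste0(prefix, layer, ".kernels")]],
                                  dim(net[[layer]]$kernels))
    net[[layer]]$biases <- arrays[[paste0(prefix, layer, ".biases")]]
  }
  for (layer in c("fc1", "fc2")) {
    net[[layer]]$weights <- matrix(arrays[[paste0(prefix, layer, ".weights")]],
                                   nrow(net[[layer]]$weights),
                                   ncol(net[[layer]]$weights))
    net[[layer]]$biases <- arrays[[paste0(prefix, layer, ".biases")]]
  }
  net
}

# Run manifest: one JSON per producing command; re-running a deterministic
# command from its manifest reproduces the outputs bit-identically.
write_manifest <- function(path, command, config, artifacts) {
  jsonlite::write_json(
    list(command = command, config = config, artifacts = artifacts,
         package_version = as.character(utils::packageVersion("copdfusion")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
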