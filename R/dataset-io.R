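# Disk interchange for datasets: 8-bit RGB PNGs, single-channel {0,255} mask
# PNGs, and a CSV manifest with columns path,label,annotation_path,
# assessment_path,split.  The same manifest shape accepts real photographs
# plus externally produced masks.

#' Write a dataset to disk as PNGs plus a CSV manifest
#'
#' Images are written as 8-bit RGB PNGs (values are quantized to 256 levels),
#' masks as single-channel PNGs with 0/255 coding.
#'
#' @param data a `"leaf_dataset"`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "leaf_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  N <- dim(data$images)[4]
  split_of <- character(N)
  for (s in names(data$splits)) split_of[data$splits[[s]]] <- s
  rows <- vector("list", N)
  for (i in seq_len(N)) {
    ip <- file.path("images", sprintf("sample_%04d.png", i))
    ap <- file.path("masks", sprintf("annotation_%04d.png", i))
    sp <- file.path("masks", sprintf("assessment_%04d.png", i))
    png::writePNG(data$images[, , , i], file.path(dir, ip))
    png::writePNG(data$annotations[, , i] * 1.0, file.path(dir, ap))
    png::writePNG(data$assessments[, , i] * 1.0, file.path(dir, sp))
    rows[[i]] <- data.frame(path = ip,
                            label = data$class_names[data$labels[i]],
                            annotation_path = ap, assessment_path = sp,
                            split = split_of[i])
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a dataset from a CSV manifest
#'
#' Loads images and masks referenced by a manifest with columns
#' `path,label,annotation_path,assessment_path,split` (paths relative to the
#' manifest's directory) into the same `"leaf_dataset"` shape the simulator
#' produces, so real photographs with externally produced masks can flow
#' through training and assessment unchanged.
#'
#' @param manifest_path path to the manifest CSV.
#' @return a `"leaf_dataset"`.
#' @export
read_manifest <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("path", "label", "annotation_path", "assessment_path", "split")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ","))
  }
  base <- dirname(manifest_path)
  N <- nrow(man)
  first <- png::readPNG(file.path(base, man$path[1]))
  U <- dim(first)[1]; V <- dim(first)[2]
  images <- array(0, c(U, V, 3L, N))
  annotations <- array(0L, c(U, V, N))
  assessments <- array(0L, c(U, V, N))
  for (i in seq_len(N)) {
    im <- png::readPNG(file.path(base, man$path[i]))
    if (length(dim(im)) == 2L) im <- array(rep(im, 3), c(dim(im), 3L))
    images[, , , i] <- im[, , 1:3]
    ann <- png::readPNG(file.path(base, man$annotation_path[i]))
    if (length(dim(ann)) == 3L) ann <- ann[, , 1]
    annotations[, , i] <- as.integer(ann > 0.5)
    ass <- png::readPNG(file.path(base, man$assessment_path[i]))
    if (length(dim(ass)) == 3L) ass <- ass[, , 1]
    assessments[, , i] <- as.integer(ass > 0.5)
  }
  class_names <- sort(unique(man$label))
  labels <- match(man$label, class_names)
  splits <- lapply(c(train = "train", validation = "validation",
                     test = "test"),
                   function(s) which(man$split == s))
  structure(list(images = images, labels = labels,
                 annotations = annotations, assessments = assessments,
                 splits = splits, class_names = class_names,
                 task = "manifest", cfg = NULL, seed = NA_integer_),
            class = "leaf_dataset")
}
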