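#' Write a labelled image set as a class-per-subdirectory tree
#'
#' Writes one lossless PNG per image under \code{root/<class>/}, plus a
#' sidecar \code{manifest.csv} (columns \code{filename,class,split,sublabel})
#' recording split tags and sub-labels, which the directory layout alone
#' cannot carry.
#'
#' @param set a [LabeledImageSet-class].
#' @param root output directory (created if needed).
#' @return \code{root}, invisibly.
#' @seealso [readImageSet()]
#' @export
writeImageSet <- function(set, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) stop(sprintf("cannot create directory '%s'", root))
  n <- nImages(set)
  cn <- classNames(set)
  for (cl in cn)
    dir.create(file.path(root, cl), showWarnings = FALSE)
  width <- max(4L, nchar(n))
  files <- character(n)
  for (i in seq_len(n)) {
    cl <- cn[imageLabels(set)[i] + 1L]
    files[i] <- file.path(cl, sprintf("img_%0*d.png", width, i))
    img <- images(set)[, , , i]
    if (length(dim(img)) == 3L && dim(img)[3L] == 1L) dim(img) <- dim(img)[1:2]
    png::writePNG(img, file.path(root, files[i]))
  }
  sub <- subLabels(set)
  manifest <- data.frame(
    filename = files,
    class = cn[imageLabels(set) + 1L],
    split = if (length(splitTags(set))) splitTags(set) else NA_character_,
    sublabel = if (is.null(sub)) NA_integer_ else sub,
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(root, "manifest.csv"),
                   row.names = FALSE)
  invisible(root)
}

#' Read a labelled image set from a directory tree
#'
#' Reads a class-per-subdirectory layout of PNG files. When a
#' \code{manifest.csv} sidecar is present (as written by
#' [writeImageSet()]), image order, split tags and sub-labels are taken
#' from it; otherwise classes are the subdirectory names in lexicographic
#' order and files are read in sorted order with no splits. All images must
#' share one size; a missing or unreadable file fails naming its path.
#'
#' @param root the dataset directory.
#' @return A [LabeledImageSet-class].
#' @export
readImageSet <- function(root) {
  if (!dir.exists(root)) stop(sprintf("directory '%s' does not exist", root))
  manifestPath <- file.path(root, "manifest.csv")
  if (file.exists(manifestPath)) {
    manifest <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
    cn <- sort(unique(manifest$class))
    files <- manifest$filename
    labels <- match(manifest$class, cn) - 1L
    split <- if (all(is.na(manifest$split))) character(0)
             else as.character(manifest$split)
    sub <- if (all(is.na(manifest$sublabel))) NULL
           else as.integer(manifest$sublabel)
  } else {
    cn <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
    if (!length(cn)) stop(sprintf("no class subdirectories under '%s'", root))
    files <- character(0); labels <- integer(0)
    for (k in seq_along(cn)) {
      fs <- sort(list.files(file.path(root, cn[k]),
                            pattern = "\\.(png|PNG)$"))
      files <- c(files, file.path(cn[k], fs))
      labels <- c(labels, rep(k - 1L, length(fs)))
    }
    split <- character(0); sub <- NULL
  }
  imgs <- NULL
  for (i in seq_along(files)) {
    p <- file.path(root, files[i])
    if (!file.exists(p))
      stop(sprintf("listed image file is missing: '%s'", p))
    im <- tryCatch(png::readPNG(p),
                   error = function(e)
                     stop(sprintf("cannot read image '%s': %s", p,
                                  conditionMessage(e)), call. = FALSE))
    if (length(dim(im)) == 2L) dim(im) <- c(dim(im), 1L)
    if (dim(im)[3L] == 4L) im <- im[, , 1:3, drop = FALSE]  # drop alpha
    if (is.null(imgs)) {
      imgs <- array(0, c(dim(im), length(files)))
    } else if (!identical(dim(im), dim(imgs)[1:3])) {
      stop(sprintf("image '%s' has size %s but earlier images are %s", p,
                   paste(dim(im), collapse = "x"),
                   paste(dim(imgs)[1:3], collapse = "x")))
    }
    imgs[, , , i] <- im
  }
  if (is.null(imgs)) stop(sprintf("no images found under '%s'", root))
  LabeledImageSet(imgs, labels, classNames = cn, subLabels = sub,
                  split = split)
}
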