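#' Barcode scheme for plate-based demultiplexing
#'
#' Describes the group/plate/column/row DNA barcodes prepended to each
#' amplicon and the order in which the four fields appear at the 5' end of
#' the merged read. Within each field all barcodes must be of equal length
#' and pairwise Hamming distance >= 2; ambiguity at the maximum tolerated
#' mismatch is resolved by the unique-best rule at demultiplexing time.
#'
#' @param group,plate,column,row Named character vectors of barcodes
#'   (names are the well-coordinate labels).
#' @param layout Order of the four fields within the read prefix.
#' @param max_mismatch Per-field mismatch tolerance for assignment.
#' @return A `barcode_scheme` object.
#' @export
barcode_scheme <- function(group, plate, column, row,
                           layout = c("group", "plate", "column", "row"),
                           max_mismatch = 1) {
  fields <- list(group = group, plate = plate, column = column, row = row)
  layout <- match.arg(layout, c("group", "plate", "column", "row"),
                      several.ok = TRUE)
  if (!setequal(layout, names(fields)) || length(layout) != 4)
    stop("layout must order the four fields group/plate/column/row")
  for (f in names(fields)) {
    bc <- fields[[f]]
    if (is.null(names(bc)) || anyDuplicated(names(bc)))
      stop("barcodes in field '", f, "' must carry unique labels")
    if (length(unique(nchar(bc))) != 1)
      stop("barcodes in field '", f, "' must be of equal length")
    if (length(bc) > 1) {
      d <- cpp_hamming_matrix(bc)
      if (min(d[upper.tri(d)]) < 2)
        stop("barcode collision in field '", f,
             "': pairwise Hamming distance < 2")
    }
  }
  structure(list(fields = fields, layout = layout,
                 max_mismatch = as.integer(max_mismatch)),
            class = "barcode_scheme")
}

#' @export
print.barcode_scheme <- function(x, ...) {
  cat("Barcode scheme:",
      paste(sprintf("%s (%d x %dnt)", x$layout,
                    lengths(x$fields)[x$layout],
                    vapply(x$fields[x$layout], function(b) nchar(b[1]), 0L)),
            collapse = " + "),
      sprintf("| max_mismatch = %d\n", x$max_mismatch))
  invisible(x)
}

scheme_prefix_width <- function(scheme) {
  sum(vapply(scheme$fields[scheme$layout], function(b) nchar(b[1]), 0L))
}

# Barcode prefix for one well id (named list/vector with the four labels).
well_prefix <- function(scheme, well) {
  paste(vapply(scheme$layout, function(f) {
    bc <- scheme$fields[[f]]
    b <- bc[[as.character(well[[f]])]]
    if (is.null(b) || is.na(b)) stop("unknown ", f, " label: ", well[[f]])
    b
  }, character(1)), collapse = "")
}

#' Default 96-well barcode scheme
#'
#' A deterministic scheme with 2 group, 2 plate, 12 column and 8 row barcodes
#' of length 6, constructed greedily so that every within-field pair is at
#' Hamming distance >= 3 (unique-best assignment is then safe at one
#' mismatch).
#'
#' @param max_mismatch Mismatch tolerance (default 1).
#' @return A `barcode_scheme`.
#' @export
default_barcode_scheme <- function(max_mismatch = 1) {
  make <- function(n, labels, seed) {
    with_seed(seed, {
      out <- character(0)
      while (length(out) < n) {
        cand <- random_nt(1, 6)
        if (length(out) == 0 || min(cpp_hamming(rep(cand, length(out)), out)) >= 3)
          out <- c(out, cand)
      }
      setNames(out, labels)
    })
  }
  barcode_scheme(
    group = make(2, c("g1", "g2"), 101),
    plate = make(2, c("p1", "p2"), 102),
    column = make(12, paste0("c", 1:12), 103),
    row = make(8, paste0("r", LETTERS[1:8]), 104),
    max_mismatch = max_mismatch)
}

#' Read / write a barcode scheme as JSON
#' @param path JSON file path.
#' @return `read_barcode_scheme` returns a `barcode_scheme`.
#' @export
read_barcode_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  barcode_scheme(group = unlist(x$fields$group), plate = unlist(x$fields$plate),
                 column = unlist(x$fields$column), row = unlist(x$fields$row),
                 layout = x$layout, max_mismatch = x$max_mismatch)
}

#' @param scheme A `barcode_scheme` to write.
#' @rdname read_barcode_scheme
#' @export
write_barcode_scheme <- function(scheme, path) {
  out <- unclass(scheme)
  out$fields <- lapply(out$fields, as.list)  # keep labels in the JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(path)
}
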