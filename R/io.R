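# Readers/writers for the tidy RPP table dialect, distance matrices,
# label images and sector polygon files.

RPP_TABLE_COLS <- c("specimen_id", "taxon", "element", "age_dph",
                    "dev_strategy", "sector", "q", "porosity")

#' Read a tidy RPP table
#'
#' Long-format CSV with one row per specimen x element x sector x quadrant;
#' columns `specimen_id, taxon, element, age_dph, dev_strategy, sector, q,
#' porosity` (`element_id` optional; constructed as specimen_id.element
#' when absent). Blank porosity cells are missing values, never zero.
#' Malformed rows (porosity outside [0, 100], quadrant not a-d,
#' non-positive sector) are rejected, not repaired, and returned in the
#' `rejected` attribute.
#'
#' @param path CSV path.
#' @return Validated long data.frame with attribute `rejected`.
#' @export
read_rpp_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  missing_cols <- setdiff(RPP_TABLE_COLS, names(tab))
  if (length(missing_cols) > 0)
    stop("RPP table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"element_id" %in% names(tab))
    tab$element_id <- paste(tab$specimen_id, tab$element, sep = ".")
  tab$porosity <- suppressWarnings(as.numeric(tab$porosity))
  tab$sector <- suppressWarnings(as.integer(tab$sector))
  bad <- (!is.na(tab$porosity) & (tab$porosity < 0 | tab$porosity > 100)) |
    !(tab$q %in% letters[1:4]) |
    is.na(tab$sector) | tab$sector < 1
  rejected <- tab[bad, , drop = FALSE]
  tab <- tab[!bad, , drop = FALSE]
  attr(tab, "rejected") <- rejected
  tab
}

#' Write a tidy RPP table
#'
#' @param table Long-format RPP data.frame.
#' @param path Output CSV path.
#' @export
write_rpp_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Collapse a long RPP table to per-element mean RPPs
#'
#' Quadrant-wise available-case averaging over sectors (an entry is missing
#' only when missing in every sector), with metadata carried along.
#'
#' @param table Long-format RPP data.frame (see [read_rpp_table()]).
#' @return An `rpp_set` data.frame: element_id, specimen_id, taxon,
#'   element, age_dph, dev_strategy, n_sectors, P_a..P_d.
#' @export
rpp_wide <- function(table) {
  stopifnot(all(c("element_id", "sector", "q", "porosity") %in% names(table)))
  split_by <- split(table, table$element_id)
  rows <- lapply(split_by, function(d) {
    prof_list <- lapply(split(d, d$sector), function(s) {
      v <- rep(NA_real_, 4)
      v[match(s$q, letters[1:4])] <- s$porosity
      v
    })
    m <- mean_rpp(prof_list)
    meta <- d[1, intersect(c("element_id", "specimen_id", "taxon", "element",
                             "age_dph", "dev_strategy"), names(d)),
              drop = FALSE]
    cbind(meta,
          data.frame(n_sectors = attr(m, "n_sectors"),
                     P_a = m[1], P_b = m[2], P_c = m[3], P_d = m[4]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rpp_set", "data.frame")
  out
}

#' Extract the n x 4 porosity matrix from an RPP set
#'
#' @param rpps An `rpp_set`, a long RPP table, or a numeric matrix with 4
#'   columns (returned unchanged, row names preserved).
#' @return Numeric matrix, rows named by element id.
#' @export
rpp_matrix <- function(rpps) {
  if (is.matrix(rpps)) {
    stopifnot(ncol(rpps) == 4)
    if (is.null(rownames(rpps)))
      rownames(rpps) <- sprintf("E%03d", seq_len(nrow(rpps)))
    return(rpps)
  }
  if (is.data.frame(rpps) && !all(c("P_a", "P_b", "P_c", "P_d") %in% names(rpps)))
    rpps <- rpp_wide(rpps)
  m <- as.matrix(rpps[, c("P_a", "P_b", "P_c", "P_d")])
  rownames(m) <- rpps$element_id
  m
}

#' Write / read a distance matrix as square CSV
#'
#' @param dm Symmetric matrix with id dimnames.
#' @param path CSV path.
#' @export
write_distance_matrix <- function(dm, path) {
  utils::write.csv(as.data.frame(dm), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

#' Write / read a label image as 8-bit greyscale PNG
#'
#' Class codes 0..6 are stored as grey levels 0..6/255; the physical pixel
#' size travels in a JSON sidecar `<path>.json`.
#'
#' @param image A `label_image`.
#' @param path PNG path.
#' @export
write_label_image <- function(image, path) {
  png::writePNG(image$raster / 255, path)
  jsonlite::write_json(list(pixel_size = image$pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  im <- png::readPNG(path)
  if (length(dim(im)) == 3) im <- im[, , 1]
  ras <- round(im * 255)
  sidecar <- paste0(path, ".json")
  px <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar)$pixel_size else 1
  label_image(ras, pixel_size = px)
}

#' Write / read sector specifications as plain text
#'
#' One block per sector: a `sector <i>` line, then for each of the four
#' boundary polylines a `<name> <n>` line followed by n `x y` vertex
#' lines.
#'
#' @param sectors List of `sector_spec`s.
#' @param path Text file path.
#' @export
write_sector_spec <- function(sectors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in sectors) {
    writeLines(sprintf("sector %d", s$sector_index), con)
    for (part in c("inner", "outer", "side1", "side2")) {
      pl <- s[[part]]
      writeLines(sprintf("%s %d", part, nrow(pl)), con)
      utils::write.table(pl, con, row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' @rdname write_sector_spec
#' @export
read_sector_spec <- function(path) {
  lines <- readLines(path)
  sectors <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (hdr[1] != "sector") stop("malformed sector file at line ", i)
    idx <- as.integer(hdr[2])
    parts <- list()
    i <- i + 1L
    for (p in 1:4) {
      ph <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      npt <- as.integer(ph[2])
      block <- lines[(i + 1L):(i + npt)]
      xy <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"),
                                  function(v) as.numeric(v[1:2])))
      parts[[ph[1]]] <- xy
      i <- i + npt + 1L
    }
    sectors[[length(sectors) + 1L]] <-
      sector_spec(parts$inner, parts$outer, parts$side1, parts$side2,
                  sector_index = idx)
  }
  sectors
}
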