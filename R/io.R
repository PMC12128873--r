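#' Read a SEG segment table
#'
#' Reads tab-delimited SEG files (sample, chrom, start, end, seg.mean; a
#' 6-column dialect with a `num.mark` column before the segment mean is
#' accepted, in which case the last column is taken as the mean). A header
#' line is detected by a non-numeric start field. Chromosome labels are
#' normalised (`chr1` and `1` become the same label). Rows with a
#' malformed numeric field or `end < start` are rejected with their line
#' number.
#'
#' @param path Path to a SEG file.
#' @return Segment `data.frame`: `sample`, `chrom`, `start_bp`, `end_bp`,
#'   `log2_ratio`.
#' @export
read_seg <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty SEG file: ", path)
    return(data.frame(sample = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      log2_ratio = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1]])
  if (ncol1 < 5) stop("SEG file must have >= 5 tab-delimited columns")
  first_start <- suppressWarnings(as.numeric(fields[[1]][3]))
  data_rows <- if (is.na(first_start)) seq_along(lines)[-1] else seq_along(lines)
  out <- lapply(data_rows, function(i) {
    f <- fields[[i]]
    if (length(f) < 5) stop("line ", i, ": fewer than 5 fields")
    start <- suppressWarnings(as.numeric(f[3]))
    end <- suppressWarnings(as.numeric(f[4]))
    mean <- suppressWarnings(as.numeric(f[length(f)]))
    if (is.na(start) || is.na(end) || is.na(mean)) {
      stop("line ", i, ": malformed numeric field")
    }
    if (end < start) stop("line ", i, ": segment end < start")
    data.frame(sample = f[1], chrom = f[2], start_bp = start, end_bp = end,
               log2_ratio = mean, stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, out)
  seg$chrom <- normalize_chrom(seg$chrom)
  seg
}

#' Write a segment table as SEG
#'
#' @param segments Segment `data.frame` (see [read_seg()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  df <- data.frame(ID = segments$sample, chrom = segments$chrom,
                   loc.start = format(segments$start_bp, scientific = FALSE, trim = TRUE),
                   loc.end = format(segments$end_bp, scientific = FALSE, trim = TRUE),
                   seg.mean = segments$log2_ratio)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-delimited.
#' Duplicate members within a set are removed with a warning; a line with
#' fewer than 3 fields is rejected with its line number; an empty file
#' yields an empty collection with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(stats::setNames(list(), character()))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("line ", i, ": GMT line needs >= 3 fields")
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("set '", f[1], "' (line ", i, "): ",
              sum(duplicated(members)), " duplicate member(s) removed")
      members <- unique(members)
    }
    sets[[f[1]]] <- members
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromosome-arm table (BED-like TSV)
#'
#' Columns: chrom, start, end, arm (header tolerated). Coordinates are
#' 1-based inclusive.
#'
#' @param path Path to the arm table.
#' @return Validated genome table (see [validate_genome()]).
#' @export
read_arm_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (suppressWarnings(is.na(as.numeric(df[1, 2])))) {
    df <- df[-1, , drop = FALSE]
  }
  g <- data.frame(chrom = as.character(df[[1]]),
                  start_bp = as.numeric(df[[2]]),
                  end_bp = as.numeric(df[[3]]),
                  arm = as.character(df[[4]]),
                  stringsAsFactors = FALSE)
  validate_genome(g)
}

#' Read per-sample purity (CSV: sample, purity)
#'
#' @param path Path to a two-column CSV.
#' @return Named numeric vector of purities.
#' @export
read_purity <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read a guide count matrix with its guide map
#'
#' @param counts_path CSV/TSV of guide counts (first column = guide id).
#' @param map_path TSV guide map: guide, gene, chrom, pos (header
#'   tolerated).
#' @return List with `counts` matrix and `map` data.frame.
#' @export
read_counts <- function(counts_path, map_path) {
  sep <- if (grepl("\\.tsv$", counts_path)) "\t" else ","
  df <- utils::read.table(counts_path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  names(map)[1:2] <- c("guide", "gene")
  list(counts = counts, map = map)
}
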