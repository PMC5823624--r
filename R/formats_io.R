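# File formats.  All tabular files are TSV: tab-separated, UTF-8, '#' comment
# lines, no quoting.  All genomic coordinates, in files and in memory, are
# 0-based half-open (BED convention).  Floats are written with 6 significant
# digits so that write/read round-trips are byte-stable.

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

.read_tsv <- function(path, col_names) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          quote = "", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(col_names, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  df
}

.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' Accepts 4+ column BED (chrom, start, end, name); coordinates are taken as
#' BED-standard 0-based half-open and are validated.
#'
#' @param path path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `id`, in file
#'   order.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), id = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 4))
    stop(sprintf("BED parse error at line %d: fewer than 4 columns",
                 which(n < 4)[1]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  id    <- vapply(fields, `[[`, "", 4L)
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop(sprintf("BED parse error at line %d: non-integer coordinates", bad[1]))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: start >= end", bad[1]))
  bad <- which(!nzchar(chrom))
  if (length(bad))
    stop(sprintf("BED parse error at line %d: empty chromosome", bad[1]))
  data.frame(chrom = chrom, start = start, end = end, id = id,
             stringsAsFactors = FALSE)
}

#' Write genomic intervals as BED4
#'
#' @param intervals data.frame with `chrom`, `start`, `end`, `id` (optionally a
#'   `direction` column, encoded into the name field as `id|gain` / `id|loss`).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  id <- if ("id" %in% names(intervals)) intervals$id
        else sprintf("iv%d", seq_len(nrow(intervals)))
  if ("direction" %in% names(intervals))
    id <- paste0(id, "|", ifelse(intervals$direction > 0, "gain", "loss"))
  lines <- sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                   as.integer(intervals$start), as.integer(intervals$end), id)
  writeLines(lines, path)
  invisible(path)
}

#' Read SEG-like per-probe CNA data
#'
#' TSV with columns `sample`, `chrom`, `start`, `end`, `value`; coordinates
#' 0-based half-open.  In `"calls"` mode values must be discrete calls in
#' \{-1, 0, 1\}; in `"ratios"` mode they are continuous log2 ratios and are
#' returned as a probe x sample numeric matrix (discretize afterwards with
#' [call_from_log_ratios()]).  Probes are the unique (chrom, start, end)
#' triples; sample x probe combinations absent from the file become missing.
#'
#' @param path path to the TSV.
#' @param mode `"calls"` or `"ratios"`.
#' @return in calls mode a [probe_call_dataset()]; in ratios mode a list with
#'   `probes` and a numeric `values` matrix.
#' @export
read_seg_calls <- function(path, mode = c("calls", "ratios")) {
  mode <- match.arg(mode)
  df <- .read_tsv(path, c("sample", "chrom", "start", "end", "value"))
  key <- paste(df$chrom, df$start, df$end, sep = ":")
  probes <- df[!duplicated(key), c("chrom", "start", "end")]
  o <- order(probes$chrom, probes$start, probes$end)
  probes <- probes[o, , drop = FALSE]
  rownames(probes) <- NULL
  pidx <- match(key, paste(probes$chrom, probes$start, probes$end, sep = ":"))
  samples <- unique(df$sample)
  m <- matrix(NA_real_, nrow(probes), length(samples),
              dimnames = list(NULL, samples))
  m[cbind(pidx, match(df$sample, samples))] <- df$value
  if (mode == "calls") {
    obs <- m[!is.na(m)]
    if (!all(obs %in% c(-1, 0, 1)))
      stop(sprintf("%s: non-call value %s in call mode", path,
                   format(obs[!(obs %in% c(-1, 0, 1))][1])))
    probe_call_dataset(probes, m)
  } else {
    list(probes = probes, values = m)
  }
}

#' Write a probe-level CNA dataset in SEG-like TSV form
#'
#' @param dataset a [probe_call_dataset()] or a list with `probes` and a
#'   numeric `values` matrix (ratios).
#' @param path output path.
#' @export
write_seg_calls <- function(dataset, path) {
  m <- if (inherits(dataset, "probe_call_dataset")) dataset$calls
       else dataset$values
  probes <- dataset$probes
  idx <- which(!is.na(m), arr.ind = TRUE)
  df <- data.frame(sample = colnames(m)[idx[, 2]],
                   chrom = probes$chrom[idx[, 1]],
                   start = as.integer(probes$start[idx[, 1]]),
                   end = as.integer(probes$end[idx[, 1]]),
                   value = .fmt_num(m[idx]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$sample, df$chrom, df$start), ]
  .write_tsv(df, path, comment = "coordinates: 0-based half-open")
}

#' Read a ranked up/down feature list
#'
#' TSV with columns `id`, `direction` (up/down) and `rank` (1-based, dense
#' within direction).  An optional header comment `# universe_size: N` records
#' how many features were eligible in the source.
#'
#' @param path path to the TSV.
#' @param normalize_mirna lowercase ids and strip -3p/-5p arm suffixes
#'   (miRNA name normalization); default FALSE.
#' @return a [ranked_study()] (with `measured = NULL`).
#' @export
read_ranked_list <- function(path, normalize_mirna = FALSE) {
  header <- grep("^#", readLines(path, n = 5L), value = TRUE)
  us <- NULL
  m <- regmatches(header, regexec("universe_size:\\s*([0-9]+)", header))
  m <- Filter(length, m)
  if (length(m)) us <- as.integer(m[[1]][2])
  df <- .read_tsv(path, c("id", "direction", "rank"))
  if (!all(df$direction %in% c("up", "down")))
    stop(sprintf("%s: direction must be 'up' or 'down'", path))
  if (normalize_mirna) df$id <- normalize_mirna_id(df$id)
  pick <- function(dir) {
    sub <- df[df$direction == dir, ]
    if (anyDuplicated(sub$id))
      stop(sprintf("%s: duplicate id '%s' in %s list", path,
                   sub$id[duplicated(sub$id)][1], dir))
    sub$id[order(sub$rank)]
  }
  ranked_study(up = pick("up"), down = pick("down"), universe_size = us)
}

#' Write a ranked study as a ranked-list TSV
#'
#' @param study a [ranked_study()].
#' @param path output path.
#' @export
write_ranked_list <- function(study, path) {
  df <- rbind(
    data.frame(id = study$up, direction = "up",
               rank = seq_along(study$up), stringsAsFactors = FALSE),
    data.frame(id = study$down, direction = "down",
               rank = seq_along(study$down), stringsAsFactors = FALSE))
  comment <- if (!is.na(study$universe_size))
    sprintf("universe_size: %d", study$universe_size)
  .write_tsv(df, path, comment = comment)
}

#' Read a feature x sample expression matrix with a class sidecar
#'
#' The matrix TSV has a header row of sample ids and a first column of feature
#' ids; the sidecar TSV has columns `sample` and `class` (tumor/normal).
#'
#' @param path matrix TSV.
#' @param class_path sidecar TSV with sample classes.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, class_path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          quote = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  cls <- .read_tsv(class_path, c("sample", "class"))
  expression_matrix(m, stats::setNames(cls$class, cls$sample))
}

#' Write an expression matrix and its class sidecar
#'
#' @param em an [expression_matrix()].
#' @param path matrix TSV output path.
#' @param class_path sidecar output path.
#' @export
write_expression_matrix <- function(em, path, class_path) {
  out <- data.frame(feature = rownames(em$values), stringsAsFactors = FALSE)
  vals <- em$values
  for (j in seq_len(ncol(vals))) out[[colnames(vals)[j]]] <- .fmt_num(vals[, j])
  .write_tsv(out, path)
  .write_tsv(data.frame(sample = names(em$sample_class),
                        class = unname(em$sample_class),
                        stringsAsFactors = FALSE), class_path)
}

#' Read a miRNA-target network table
#'
#' TSV with columns `mirna`, `gene`, `score` (prediction confidence in (0, 1])
#' and optionally `n_sources`.  Confidence filtering of the kind used when
#' exporting from an integrated target database (keep only the most confident
#' predictions supported by several sources) is applied at load time.
#'
#' @param path path to the TSV.
#' @param min_score drop edges with score below this value (NULL = keep all).
#' @param min_sources drop edges with fewer supporting sources (needs an
#'   `n_sources` column; NULL = keep all).
#' @param normalize_mirna lowercase miRNA ids and strip arm suffixes.
#' @return data.frame of edges with columns `mirna`, `gene`, `score`
#'   (+ `n_sources` when present).
#' @export
read_target_network <- function(path, min_score = NULL, min_sources = NULL,
                                normalize_mirna = FALSE) {
  df <- .read_tsv(path, c("mirna", "gene", "score"))
  if (normalize_mirna) df$mirna <- normalize_mirna_id(df$mirna)
  if (!is.null(min_score)) df <- df[df$score >= min_score, , drop = FALSE]
  if (!is.null(min_sources)) {
    if (!"n_sources" %in% names(df))
      stop("min_sources filter requires an n_sources column")
    df <- df[df$n_sources >= min_sources, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_target_network
#' @param edges data.frame of edges to write.
#' @export
write_target_network <- function(edges, path) {
  edges$score <- .fmt_num(edges$score)
  .write_tsv(edges, path)
}

#' Read / write the planted-truth table of a synthetic cohort
#'
#' TSV with columns `gene`, `de_direction`, `region_direction`, `is_paradox`.
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
read_truth <- function(path) {
  df <- .read_tsv(path, c("gene", "de_direction", "region_direction",
                          "is_paradox"))
  df$is_paradox <- as.logical(df$is_paradox)
  df
}

#' @rdname read_truth
#' @param truth data.frame as returned by [simulate_cohort()]'s `truth$table`.
#' @export
write_truth <- function(truth, path) .write_tsv(truth, path)

#' Normalize miRNA identifiers
#'
#' Lowercases and strips trailing "-3p"/"-5p" arm suffixes.  This is a
#' pragmatic stand-in for full database alias resolution, sufficient to match
#' names across study lists that report arms inconsistently.
#'
#' @param x character vector of miRNA names.
#' @param strip_arm strip -3p/-5p suffixes (default TRUE).
#' @return normalized character vector.
#' @export
normalize_mirna_id <- function(x, strip_arm = TRUE) {
  x <- tolower(x)
  if (strip_arm) x <- sub("-[35]p$", "", x)
  x
}
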