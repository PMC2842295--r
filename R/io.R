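#' Read a FASTA file
#'
#' Sequences are uppercased, U is mapped to T, and any other non-ACGT
#' character becomes N. Record names are the first whitespace-delimited
#' word of each header. An empty file yields an empty collection with a
#' warning; a file whose first non-blank line is not a header is
#' rejected with its line number.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop("malformed FASTA at line ", nonblank[1L],
         ": expected a '>' header before sequence data")
  }
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  seqs <- chartr("U", "T", seqs)
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  nms <- names(sequences)
  if (is.null(nms)) nms <- paste0("seq", seq_along(sequences))
  for (k in seq_along(sequences)) {
    writeLines(paste0(">", nms[k]), con)
    s <- sequences[[k]]
    starts <- seq.int(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read aligned sites from one-sequence-per-line text
#'
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path input path.
#' @param source_ids optional origin labels, one per kept line.
#' @return a [site_alignment()].
#' @export
read_sites_text <- function(path, source_ids = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  site_alignment(lines, source_ids = source_ids)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Serialise / read a PWM
#'
#' Text format: a header `# PWM L=<L> pseudocount=<kappa>`, then L
#' whitespace-separated probability rows in A C G T order. Entries are
#' written with 17 significant digits, so a round trip is bit-exact.
#'
#' @param pwm a [pwm()].
#' @param path file path.
#' @return `write_pwm` returns `path` invisibly; `read_pwm` the
#'   [pwm()].
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(inherits(pwm, "pwm"))
  lines <- c(sprintf("# PWM L=%d pseudocount=%s", nrow(pwm$probs),
                     fmt_num(pwm$pseudocount)),
             apply(pwm$probs, 1L, function(r) paste(fmt_num(r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

parse_header <- function(line, tag) {
  if (!grepl(paste0("^# ", tag, " "), line)) {
    stop("not a ", tag, " file (bad header: '", line, "')")
  }
  kv <- regmatches(line, gregexpr("[A-Za-z_]+=[^ ]+", line))[[1L]]
  vals <- sub("^[A-Za-z_]+=", "", kv)
  names(vals) <- sub("=.*$", "", kv)
  vals
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  h <- parse_header(lines[1L], "PWM")
  L <- as.integer(h[["L"]])
  probs <- do.call(rbind, lapply(lines[1L + seq_len(L)], function(x)
    as.numeric(strsplit(trimws(x), "\\s+")[[1L]])))
  pwm(probs, as.numeric(h[["pseudocount"]]))
}

#' Serialise / read a DWM
#'
#' Structured text: a `# DWM L=<L> prior_mass=<m>` header, the marginal
#' PWM block (as in [write_pwm()]), then for each stored pair a line
#' `pair <i> <j>` followed by 4 rows of 4 joint probabilities (row =
#' base at i, column = base at j, A C G T order).
#'
#' @param dwm a [dwm()].
#' @param path file path.
#' @return `write_dwm` returns `path` invisibly; `read_dwm` the
#'   [dwm()].
#' @export
write_dwm <- function(dwm, path) {
  stopifnot(inherits(dwm, "dwm"))
  L <- motif_length(dwm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# DWM L=%d prior_mass=%s", L, fmt_num(dwm$prior_mass)), con)
  writeLines(sprintf("# PWM L=%d pseudocount=%s", L,
                     fmt_num(dwm$marginal$pseudocount)), con)
  writeLines(apply(dwm$marginal$probs, 1L, function(r)
    paste(fmt_num(r), collapse = " ")), con)
  for (i in seq_len(L - 1L)) {
    for (j in seq.int(i + 1L, L)) {
      writeLines(sprintf("pair %d %d", i, j), con)
      writeLines(apply(dwm_pair(dwm, i, j), 1L, function(r)
        paste(fmt_num(r), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' @rdname write_dwm
#' @export
read_dwm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  h <- parse_header(lines[1L], "DWM")
  L <- as.integer(h[["L"]])
  hm <- parse_header(lines[2L], "PWM")
  probs <- do.call(rbind, lapply(lines[2L + seq_len(L)], function(x)
    as.numeric(strsplit(trimws(x), "\\s+")[[1L]])))
  marg <- pwm(probs, as.numeric(hm[["pseudocount"]]))
  pairs <- vector("list", (L * (L - 1L)) %/% 2L)
  cursor <- 2L + L
  while (cursor < length(lines)) {
    stopifnot(startsWith(lines[cursor + 1L], "pair "))
    ij <- as.integer(strsplit(lines[cursor + 1L], "\\s+")[[1L]][2:3])
    tab <- do.call(rbind, lapply(lines[cursor + 1L + 1:4], function(x)
      as.numeric(strsplit(trimws(x), "\\s+")[[1L]])))
    pairs[[pair_index(ij[1L], ij[2L], L)]] <- tab
    cursor <- cursor + 5L
  }
  dwm(pairs, marg, as.numeric(h[["prior_mass"]]))
}

#' Read / write BED6-like site tables
#'
#' Tab-separated, no header: sequence_id, start, end, name, logodds
#' (score), strand. Coordinates are 0-based half-open throughout the
#' package.
#'
#' @param sites data.frame of scored sites.
#' @param path file path.
#' @return `write_sites` returns `path` invisibly; `read_sites` the
#'   data.frame.
#' @export
write_sites <- function(sites, path) {
  df <- sites[, c("sequence_id", "start", "end", "name", "logodds", "strand")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("sequence_id", "start", "end",
                                        "name", "logodds", "strand"))
  df
}

#' Read / write a deviation table
#'
#' Tab-separated with header, mirroring [pair_deviation_stats()] output
#' (plus any extra columns such as `factor`).
#'
#' @param devs deviation data.frame.
#' @param path file path.
#' @return `write_deviation_table` returns `path` invisibly;
#'   `read_deviation_table` the data.frame.
#' @export
write_deviation_table <- function(devs, path) {
  utils::write.table(devs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_deviation_table
#' @export
read_deviation_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a per-probe binding p-value table
#'
#' Delimited text with one row per probe: a probe-id column and one
#' numeric p-value column per condition. The delimiter is sniffed from
#' the header line (tab or comma), matching both TSV exports and the
#' published comma-separated yeast layout.
#'
#' @param path file path.
#' @param probe_col name of the probe-id column (default: the first
#'   column).
#' @return data.frame with the probe-id column named `probe`.
#' @export
read_binding_table <- function(path, probe_col = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(probe_col)) probe_col <- names(df)[1L]
  names(df)[names(df) == probe_col] <- "probe"
  df
}

#' Convert between log-odds matrices and PWMs
#'
#' A log-odds matrix stores `lambda[i, a] = ln(w[i, a] / b[a])` against
#' a stated background (the dialect used by published prior motif
#' collections). `convert_logodds_to_pwm` inverts it:
#' `w[i, a] = b[a] exp(lambda[i, a]) / sum_b b[b] exp(lambda[i, b])`,
#' with max-subtraction so large entries cannot overflow.
#'
#' @param logodds L x 4 matrix of natural-log odds (A C G T columns).
#' @param background a [background_model()].
#' @return `convert_logodds_to_pwm`: a [pwm()] (pseudocount 0);
#'   `pwm_to_logodds`: an L x 4 log-odds matrix.
#' @export
convert_logodds_to_pwm <- function(logodds, background = background_model()) {
  logodds <- as.matrix(logodds)
  if (ncol(logodds) != 4L) stop("a log-odds matrix needs 4 columns")
  if (any(!is.finite(logodds))) stop("log-odds entries must be finite")
  bg <- as_background(background)
  probs <- t(apply(logodds, 1L, function(lam) {
    v <- lam + log(bg)
    v <- v - max(v)
    e <- exp(v)
    e / sum(e)
  }))
  pwm(probs, pseudocount = 0)
}

#' @rdname convert_logodds_to_pwm
#' @param pwm a [pwm()] with strictly positive entries.
#' @export
pwm_to_logodds <- function(pwm, background = background_model()) {
  stopifnot(inherits(pwm, "pwm"))
  if (any(pwm$probs <= 0)) stop("PWM entries must be positive to take log-odds")
  bg <- as_background(background)
  sweep(log(pwm$probs), 2L, log(bg), "-")
}

#' Read a log-odds matrix file
#'
#' Same row layout as [read_pwm()] but with a `# LOGODDS L=<L>` header
#' and natural-log-odds entries.
#'
#' @param path file path.
#' @return L x 4 numeric matrix.
#' @export
read_logodds_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  h <- parse_header(lines[1L], "LOGODDS")
  L <- as.integer(h[["L"]])
  do.call(rbind, lapply(lines[1L + seq_len(L)], function(x)
    as.numeric(strsplit(trimws(x), "\\s+")[[1L]])))
}
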