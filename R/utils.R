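# Shared internal helpers. Sequence positions reported to users follow the
# conventions documented per function: genomic interchange formats are
# 0-based half-open (segment tables, BED), GRanges are 1-based inclusive,
# and within-sequence positions (seed sites, ORF starts) are 0-based.

# 0-based half-open -> IRanges (1-based inclusive)
.zeroToOne <- function(start0, end0) IRanges::IRanges(start0 + 1L, end0)

# 1-based inclusive -> 0-based half-open (returns list start/end)
.oneToZero <- function(start1, end1) list(start = start1 - 1L, end = end1)

.asDnaChar <- function(x) {
  x <- toupper(as.character(x))
  gsub("U", "T", x, fixed = TRUE)
}

.checkAcgt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", .asDnaChar(x))
  if (any(bad))
    stop(what, " contains non-ACGT symbols: ",
         paste(utils::head(names(x)[bad], 3L), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

.revcompChar <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Hamming distance between equal-length strings; Inf if lengths differ
.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# cyclic substring of `s` starting at 0-based position `from`, length `len`
.cyclicSubstr <- function(s, from, len) {
  L <- nchar(s)
  from <- from %% L
  reps <- strrep(s, ceiling((from + len) / L))
  substr(reps, from + 1L, from + len)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# uniform integer draw on [lo, hi]; safe when lo == hi (avoids R's
# scalar-sample expansion)
.sampleRange <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# run `code` under `seed` without disturbing the caller's RNG stream;
# seed = NULL uses (and advances) the current stream
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic rank: best score first, ties by id (lexicographic)
.rankByScore <- function(scores) {
  ids <- names(scores)
  ord <- order(-scores, ids)
  r <- integer(length(scores))
  r[ord] <- seq_along(scores)
  stats::setNames(r, ids)
}
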