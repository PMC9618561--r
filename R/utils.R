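# internal helpers shared across modules

STOP_CODONS <- c("TAA", "TAG", "TGA")

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
}

# the 61 sense codons, in a fixed order (lookup is deterministic)
sense_codons <- function() {
  gc <- .codon_table()
  sort(names(gc)[gc != "*"])
}

#' @noRd
bcr_error <- function(msg, class) {
  stop(structure(
    class = c(class, "bcr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# run `code` under a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Deterministic half-up rounding (`0.005 -> 0.01` at two digits), unlike
#' [base::round()]'s round-half-to-even. Used wherever reported percentages
#' are rounded, so printed summaries are reproducible to the digit.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return `x` rounded half-up to `digits` places.
#' @export
#' @examples
#' round_half_up(0.125, 2)   # 0.13
#' round_half_up(39.4, 0)    # 39
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# translate a vector of nt strings (length trimmed to a codon multiple)
translate_nt <- function(nt) {
  gc <- .codon_table()
  vapply(nt, function(s) {
    n <- nchar(s)
    n <- n - n %% 3L
    if (n == 0L) return("")
    cod <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- gc[cod]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# n random in-frame segments of len_range codons, avoiding stop codons and
# (optionally) any segment whose translation contains `motif`
random_inframe_segments <- function(n, len_range, motif = NULL) {
  if (n == 0L) return(character(0))
  sense <- sense_codons()
  gc <- .codon_table()
  lens <- if (length(len_range) == 1L) rep(as.integer(len_range), n)
          else sample(len_range, n, replace = TRUE)
  out <- character(n)
  for (l in unique(lens)) {
    idx <- which(lens == l)
    draw <- function(k) {
      m <- matrix(sample(sense, k * l, replace = TRUE), nrow = k, ncol = l)
      nt <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
      aa <- do.call(paste0, as.data.frame(matrix(gc[m], nrow = k),
                                          stringsAsFactors = FALSE))
      list(nt = nt, aa = aa)
    }
    d <- draw(length(idx))
    if (!is.null(motif)) {
      for (iter in 1:25) {
        bad <- grepl(motif, d$aa, fixed = TRUE)
        if (!any(bad)) break
        redo <- draw(sum(bad))
        d$nt[bad] <- redo$nt
        d$aa[bad] <- redo$aa
      }
    }
    out[idx] <- d$nt
  }
  out
}

# write a data.frame as TSV atomically (write to temp, then rename)
write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    bcr_error(sprintf("could not write '%s'", path), "io_error")
  }
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
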