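`%||%` <- function(a, b) if (is.null(a)) b else a

## Named substream seeds: every generator derives its own seed from the root
## seed plus a stream label, so adding one generator never perturbs the
## random draws of another.  Result stays strictly below 2^31 - 1.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.double(seed)) * 48271 + h * 9973) %% 2147483399) + 1L
}

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  as.double(x)
}

## Fixed-format TSV writer so repeated runs are byte-identical.
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
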