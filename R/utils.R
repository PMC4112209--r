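TE_FAMILIES <- c("LTR", "non-LTR", "DNA", "Helitron")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in a pipeline run flows from one root seed; each stage or
#' per-sample task derives its own 32-bit sub-seed from the root seed and a
#' label, so stages can be rerun independently yet reproducibly.
#'
#' @param seed integer root seed.
#' @param label character label of the stage or task.
#' @return an integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, keeps the result a valid R integer
  h <- as.double(seed %% m)
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer(h)
}

# Deterministic short hex digest of an R object (config fingerprinting):
# modular polynomial hash over the serialized bytes; stable across runs for
# identical configs.
object_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 3L)
  # skip serialization header (R version fields)
  bytes <- as.integer(bytes[-seq_len(14L)])
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Write a data.frame as TSV with '#'-prefixed provenance header lines.
write_tsv_header <- function(dt, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  close(con)
  on.exit(NULL)
  data.table::fwrite(dt, path, sep = "\t", append = length(header) > 0,
                     col.names = TRUE)
  invisible(path)
}

read_tsv_header <- function(path) {
  head_lines <- readLines(path, n = 100L)
  nskip <- sum(cumprod(startsWith(head_lines, "#")))
  data.table::fread(path, sep = "\t", header = TRUE, skip = nskip)
}

assert_families <- function(x) {
  bad <- setdiff(unique(x), TE_FAMILIES)
  if (length(bad))
    stop("unknown TE family label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(TE_FAMILIES, collapse = ", "), ")")
  invisible(x)
}
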