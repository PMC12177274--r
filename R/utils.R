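#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median pchisq pt rbinom rexp rmultinom rnbinom rnorm
#'   runif sd setNames reorder t.test var.test wilcox.test shapiro.test binom.test
#'   chisq.test lm coef confint p.adjust rpois as.dist
NULL

# taxon label = everything before the first "@"; "@" is reserved
taxon_of <- function(labels) sub("@.*$", "", labels)

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_seed <- function(seed) {
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1L || is.na(seed)))
    abort("`seed` must be a single number or NULL.")
  invisible(seed)
}

# run `expr` under `seed` without disturbing the caller's RNG state;
# NULL seed uses (and advances) the current stream
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Read and write FASTA files of nucleotide sequences
#'
#' Thin wrappers around [ape::read.FASTA()] / [ape::write.FASTA()] that move
#' between files and the tibble representation (`id`, `seq`) used throughout
#' the package.
#'
#' @param path File path.
#' @param records A tibble with character columns `id` and `seq`.
#' @return `read_fasta()` returns a tibble with columns `id` and `seq`;
#'   `write_fasta()` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  tibble(
    id  = names(dna),
    seq = toupper(vapply(as.character(dna), paste0, "", collapse = ""))
  )
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  dna <- ape::as.DNAbin(lapply(
    setNames(records$seq, records$id),
    function(s) strsplit(tolower(s), "")[[1]]
  ))
  ape::write.FASTA(dna, path)
  invisible(path)
}
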