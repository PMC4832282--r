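#' Derive independent child seeds from a master seed
#'
#' Deterministically expands one integer seed into `n` child seeds (each in
#' `[1, 2^30]`) so that every stochastic stage of a run gets its own stream
#' while the whole run stays reproducible from a single `--seed`.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
deriveSeeds <- function(seed, n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed) %% .Machine$integer.max)
    sample.int(2^30, n)
}

## Atomic write: write to a temp file in the same directory, then rename.
.writeAtomic <- function(writer, path) {
    tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
    writer(tmp)
    file.rename(tmp, path)
    invisible(path)
}

## TSV writer used by the CLI outputs.
.writeTsv <- function(x, path) {
    .writeAtomic(function(tmp)
        data.table::fwrite(x, tmp, sep = "\t", quote = FALSE, na = "NA"),
        path)
}
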