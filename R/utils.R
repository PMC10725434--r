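# Internal helpers: seeded evaluation, seed derivation, run manifests.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#' @noRd
with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-index child seed, kept under 2^31.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + 7919 * as.numeric(i)) %% 2147483629L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)

#' Write a reproducibility manifest next to run outputs
#'
#' Records the configuration snapshot, every seed in play, the package
#' version and digests of the input files, so any run can be replayed.
#'
#' @param path output file (JSON).
#' @param subcommand name of the operation being recorded.
#' @param config named list of configuration values (seeds included).
#' @param inputs character vector of input file paths to digest (optional).
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, subcommand, config, inputs = character()) {
  inputs <- inputs[file.exists(inputs)]
  man <- list(
    subcommand = subcommand,
    package = "brainage3d",
    version = as.character(utils::packageVersion("brainage3d")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_digests = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else {
      structure(list(), names = character())
    }
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(man)
}
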