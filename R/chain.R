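#' Construct a transmission chain
#'
#' A chain is an ordered sequence of string sets: generation 0 is the seeded
#' initial set, generations 1..G are successive recalled outputs. All
#' generations must contain the same number of items and use alphabets of
#' one size.
#'
#' @param generations List of `string_set`s, generation 0 first.
#' @param chain_id Optional identifier.
#' @return A `chain`.
#' @export
chain <- function(generations, chain_id = NULL) {
  if (!is.list(generations) || length(generations) < 1L) {
    stop("`generations` must be a nonempty list of string sets")
  }
  generations <- lapply(generations, as_string_set)
  n_items <- vapply(generations, length, integer(1))
  if (length(unique(n_items)) != 1L) {
    stop("all generations must contain the same number of items")
  }
  alpha_sizes <- vapply(generations, function(s) length(s$alphabet), integer(1))
  if (length(unique(alpha_sizes)) != 1L) {
    stop("all generations must use alphabets of one size")
  }
  structure(list(generations = generations, chain_id = chain_id),
            class = "chain")
}

#' @rdname chain
#' @param x A `chain`.
#' @export
n_generations <- function(x) {
  stopifnot(inherits(x, "chain"))
  length(x$generations) - 1L
}

#' @rdname chain
#' @param g Generation index, 0 to `n_generations(x)`.
#' @export
generation <- function(x, g) {
  stopifnot(inherits(x, "chain"))
  if (!is_whole_number(g) || g < 0 || g > n_generations(x)) {
    stop("`g` must be between 0 and ", n_generations(x))
  }
  x$generations[[g + 1L]]
}

#' @export
print.chain <- function(x, ...) {
  cat(sprintf("<chain%s: generations 0..%d, %d items per set>\n",
              if (!is.null(x$chain_id)) paste0(" ", x$chain_id) else "",
              n_generations(x), length(x$generations[[1L]])))
  invisible(x)
}

#' Read and write string-set files
#'
#' A string-set file is UTF-8 plain text, one string per line: contiguous
#' characters for letter/digit material, whitespace-separated tokens in
#' tokenized (e.g. part-of-speech) mode.
#'
#' @param path File path.
#' @param tokenized If `TRUE`, split lines on whitespace into token symbols.
#' @param kind Passed to [string_set()].
#' @return `read_string_set()` returns a `string_set`; `write_string_set()`
#'   invisibly returns `path`.
#' @export
read_string_set <- function(path, tokenized = FALSE, kind = c("generic", "experiment")) {
  kind <- match.arg(kind)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no strings found in ", path)
  items <- if (tokenized) strsplit(lines, "\\s+") else lines
  string_set(items, kind = kind)
}

#' @rdname read_string_set
#' @param s A `string_set`.
#' @export
write_string_set <- function(s, path) {
  s <- as_string_set(s)
  writeLines(as.character(s), path, useBytes = TRUE)
  invisible(path)
}

#' Read and write chain directories
#'
#' A chain on disk is a directory holding one string-set file per generation
#' (`gen00.txt`, `gen01.txt`, ...) plus a JSON `manifest.json` recording the
#' chain id, alphabet and seed provenance.
#'
#' @param dir Directory path.
#' @param tokenized Passed to [read_string_set()].
#' @return `read_chain()` returns a `chain`; `write_chain()` invisibly
#'   returns `dir`.
#' @export
read_chain <- function(dir, tokenized = FALSE) {
  if (!dir.exists(dir)) stop("chain directory not found: ", dir)
  files <- sort(list.files(dir, pattern = "^gen[0-9]+\\.txt$", full.names = TRUE))
  if (!length(files)) stop("no generation files (genNN.txt) in ", dir)
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  kind <- if (!is.null(manifest$kind)) manifest$kind else "experiment"
  gens <- lapply(files, function(f) {
    s <- tryCatch(read_string_set(f, tokenized = tokenized, kind = kind),
                  error = function(e) {
                    stop("malformed generation file ", basename(f), ": ",
                         conditionMessage(e), call. = FALSE)
                  })
    if (kind == "experiment" && anyDuplicated(as.character(s))) {
      stop("generation file ", basename(f), " contains duplicate strings",
           call. = FALSE)
    }
    s
  })
  chain(gens, chain_id = manifest$chain_id)
}

#' @rdname read_chain
#' @param x A `chain`.
#' @param seed Optional seed provenance to record in the manifest.
#' @export
write_chain <- function(x, dir, seed = NULL) {
  stopifnot(inherits(x, "chain"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in 0:n_generations(x)) {
    write_string_set(generation(x, g), file.path(dir, sprintf("gen%02d.txt", g)))
  }
  manifest <- list(
    chain_id = x$chain_id,
    kind = generation(x, 0L)$kind,
    alphabet = generation(x, 0L)$alphabet,
    n_generations = n_generations(x),
    n_items = length(generation(x, 0L)),
    seed = seed,
    package_version = as.character(utils::packageVersion("seqchains"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}
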