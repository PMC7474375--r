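## Gene sets and GMT input/output.

#' Construct a gene set
#'
#' @param name set name.
#' @param members character vector of gene identifiers; duplicates are
#'   removed, order of first appearance kept.
#' @param description free-text description (second GMT column).
#' @return An object of class `gene_set` with fields `name`, `description`,
#'   `members`.
#' @export
gene_set <- function(name, members, description = "") {
  members <- unique(as.character(members))
  members <- members[nzchar(members)]
  if (length(members) == 0) stop("gene set '", name, "' has no members")
  structure(
    list(name = as.character(name), description = as.character(description),
         members = members),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$members)))
  cat("  ", paste(head(x$members, 8), collapse = ", "),
      if (length(x$members) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

as_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else unique(as.character(x))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name <tab> description <tab> member...`.
#' Duplicate members within a line are dropped.
#'
#' @param path path to the GMT file.
#' @return A named list of [gene_set] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 3) {
      stop(sprintf("GMT line %d has %d fields; at least 3 required", i, length(p)))
    }
    gene_set(p[1], p[-(1:2)], description = p[2])
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets a list of [gene_set] objects (or character vectors, named).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (!inherits(s, "gene_set")) {
      s <- gene_set(names(sets)[i], s)
    }
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
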