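#' Read a NEXUS morphological character matrix
#'
#' Parses a NEXUS CHARACTERS/DATA block (sequential or interleaved, via
#' \pkg{ape}) into a [character_matrix()]. The gap symbol `-` (inapplicable)
#' is treated exactly like `?` (missing): both become `NA`. Declared
#' dimensions (`NTAX`/`NCHAR`) and the declared symbol set are checked against
#' the parsed matrix, and duplicated taxa are a hard error.
#'
#' @param path NEXUS file
#' @param meta_path optional TSV with columns `char_id`, `stage`, `organ`
#'   (and optionally `label`), joined to characters by position of `char_id`.
#' @return a [character_matrix()]
#' @export
read_character_matrix <- function(path, meta_path = NULL) {
  raw <- tryCatch(
    { tmp <- NULL; utils::capture.output(tmp <- ape::read.nexus.data(path)); tmp },
    error = function(e) {
      stop("failed to parse NEXUS matrix ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (length(raw) == 0L || length(raw[[1]]) == 0L) {
    stop("no characters in NEXUS matrix: ", path)
  }
  lens <- lengths(raw)
  if (length(unique(lens)) != 1L) {
    stop("ragged NEXUS matrix: taxa differ in character count (",
         paste(range(lens), collapse = " vs "), ")")
  }
  decl <- .nexus_declared(path)
  if (!is.na(decl$ntax) && decl$ntax != length(raw)) {
    stop("declared NTAX=", decl$ntax, " but matrix has ", length(raw), " taxa")
  }
  if (!is.na(decl$nchar) && decl$nchar != lens[1]) {
    stop("declared NCHAR=", decl$nchar, " but matrix has ", lens[1],
         " characters")
  }
  symb <- vapply(raw, paste, character(1), collapse = "")
  used <- unique(strsplit(paste(symb, collapse = ""), "")[[1]])
  allowed <- c(decl$symbols, "?", "-")
  bad <- setdiff(used, allowed)
  if (length(decl$symbols) && length(bad)) {
    stop("undeclared symbol(s) in matrix: ", paste(bad, collapse = ", "))
  }
  states <- do.call(rbind, lapply(raw, function(x) {
    x[x %in% c("?", "-")] <- NA_character_
    suppressWarnings(as.integer(x))
  }))
  rownames(states) <- names(raw)
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- read_metadata(meta_path)
    if (nrow(meta) != ncol(states)) {
      stop("metadata lists ", nrow(meta), " characters but matrix has ",
           ncol(states))
    }
  }
  character_matrix(states, char_meta = meta)
}

# Declared dimensions and symbol alphabet from the raw NEXUS text.
.nexus_declared <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  grab <- function(re) {
    m <- regmatches(txt, regexpr(re, txt, ignore.case = TRUE, perl = TRUE))
    if (length(m)) as.integer(sub(".*=", "", m)) else NA_integer_
  }
  sy <- regmatches(txt, regexpr('symbols\\s*=\\s*"[^"]*"', txt,
                                ignore.case = TRUE, perl = TRUE))
  symbols <- if (length(sy)) {
    strsplit(gsub('.*"([^"]*)".*', "\\1", sy), "")[[1]]
  } else character(0)
  symbols <- setdiff(symbols, " ")
  list(ntax = grab("NTAX\\s*=\\s*[0-9]+"),
       nchar = grab("NCHAR\\s*=\\s*[0-9]+"),
       symbols = symbols)
}

#' Read a character metadata table
#'
#' @param path TSV with columns `char_id`, `stage`, `organ` and optionally
#'   `label`.
#' @return tibble
#' @export
read_metadata <- function(path) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
  need <- c("char_id", "stage", "organ")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("metadata file lacks column(s): ", paste(miss, collapse = ", "))
  }
  tibble::as_tibble(meta)
}

#' Write a character matrix as NEXUS (+ metadata TSV)
#'
#' @param cm a [character_matrix()]
#' @param path output NEXUS file
#' @param meta_path optional path for the stage/organ metadata TSV
#' @return `path`, invisibly
#' @export
write_character_matrix <- function(cm, path, meta_path = NULL) {
  stopifnot(inherits(cm, "character_matrix"))
  lst <- lapply(seq_len(nrow(cm$states)),
                function(i) ifelse(is.na(cm$states[i, ]), "?",
                                   as.character(cm$states[i, ])))
  names(lst) <- cm$taxa
  ape::write.nexus.data(lst, path, format = "standard", interleaved = FALSE)
  if (!is.null(meta_path)) {
    write_table(cm$char_meta, meta_path)
  }
  invisible(path)
}

#' Read one rooted phylogeny
#'
#' Reads a newick or NEXUS tree file. If `outgroup` is given the tree is
#' (re)rooted on the branch subtending the outgroup clade, so the outgroup is
#' sister to everything else; an unrooted tree without an outgroup is an
#' error. If the file holds several trees the first is returned (use
#' [read_trees()] for the full set).
#'
#' @param path tree file (newick or NEXUS)
#' @param outgroup optional character vector of outgroup taxon labels
#' @return an `ape::phylo`, rooted
#' @export
read_tree <- function(path, outgroup = NULL) {
  trees <- read_trees(path, outgroup = outgroup)
  trees[[1]]
}

#' Read a set of rooted phylogenies
#'
#' @inheritParams read_tree
#' @return list of rooted `phylo` objects
#' @export
read_trees <- function(path, outgroup = NULL) {
  trees <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(trees)) {
    trees <- tryCatch(ape::read.nexus(path), error = function(e) NULL)
  }
  if (is.null(trees)) stop("could not parse tree file: ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  lapply(trees, root_with_outgroup, outgroup = outgroup)
}

#' Root a tree with an outgroup
#'
#' @param phy an `ape::phylo`
#' @param outgroup taxon labels forming the outgroup; `NULL` keeps the tree
#'   as is (it must already be rooted).
#' @return rooted `phylo`
#' @export
root_with_outgroup <- function(phy, outgroup = NULL) {
  if (!is.null(outgroup)) {
    missing <- setdiff(outgroup, phy$tip.label)
    if (length(missing)) {
      stop("outgroup taxa not in tree: ", paste(missing, collapse = ", "))
    }
    phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  }
  if (!ape::is.rooted(phy)) {
    stop("tree is unrooted and no outgroup was given")
  }
  phy
}

#' Align a tree with the taxa of a character matrix
#'
#' Tips absent from the matrix are pruned with a warning; matrix taxa absent
#' from the tree are a hard error (states would be silently lost otherwise).
#'
#' @param phy rooted `phylo`
#' @param cm a [character_matrix()]
#' @return a `phylo` whose tip set equals the matrix taxa
#' @export
match_tree_matrix <- function(phy, cm) {
  stopifnot(inherits(cm, "character_matrix"))
  extra <- setdiff(phy$tip.label, cm$taxa)
  absent <- setdiff(cm$taxa, phy$tip.label)
  if (length(absent)) {
    stop("matrix taxa missing from tree: ", paste(absent, collapse = ", "))
  }
  if (length(extra)) {
    warning("pruning ", length(extra), " tip(s) absent from the matrix: ",
            paste(head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ...")
    phy <- ape::drop.tip(phy, extra)
  }
  phy
}

#' Write a result table as TSV
#'
#' Tab-separated UTF-8 with a single header line and the column order of the
#' input; an empty table yields a header-only file.
#'
#' @param x data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
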