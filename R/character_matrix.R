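#' Discrete morphological character matrix
#'
#' A `character_matrix` bundles a taxa-by-characters table of small integer
#' state codes (`NA` = missing or inapplicable, written `?` in NEXUS) with
#' per-character metadata: a character id, a free-text label, the
#' developmental stage at which the character is expressed (egg, L1, L2, L3,
#' pupa or adult) and, for adult characters only, the body part (head, thorax,
#' abdomen, male or female terminalia).
#'
#' @param states integer matrix (or coercible), taxa in rows, characters in
#'   columns. Row names are taxon labels; missing entries are `NA`. State
#'   codes must lie in 0..8, the single-digit NEXUS symbol range used for
#'   morphological data.
#' @param char_meta optional data frame with columns `char_id`, and optionally
#'   `label`, `stage`, `organ`. Defaults are generated when absent.
#' @param taxa optional character vector of taxon labels overriding row names.
#'
#' @return an object of class `character_matrix` with elements `states`
#'   (integer matrix), `taxa` (character vector) and `char_meta` (tibble).
#' @export
character_matrix <- function(states, char_meta = NULL, taxa = NULL) {
  states <- as.matrix(states)
  mode(states) <- "integer"
  if (is.null(taxa)) taxa <- rownames(states)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(states)))
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon label(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  rownames(states) <- taxa
  if (is.null(colnames(states))) {
    colnames(states) <- paste0("c", seq_len(ncol(states)))
  }
  if (any(!is.na(states))) {
    rng <- range(states, na.rm = TRUE)
    if (rng[1] < 0L || rng[2] > 8L) {
      stop("state codes must be integers in 0..8; found range ",
           rng[1], "..", rng[2])
    }
  }
  if (is.null(char_meta)) {
    char_meta <- tibble::tibble(char_id = colnames(states))
  }
  char_meta <- tibble::as_tibble(char_meta)
  if (!"char_id" %in% names(char_meta)) {
    stop("char_meta must have a 'char_id' column")
  }
  char_meta$char_id <- as.character(char_meta$char_id)
  if (!"label" %in% names(char_meta)) char_meta$label <- char_meta$char_id
  if (!"stage" %in% names(char_meta)) char_meta$stage <- NA_character_
  if (!"organ" %in% names(char_meta)) char_meta$organ <- NA_character_
  if (nrow(char_meta) != ncol(states)) {
    stop("char_meta has ", nrow(char_meta), " rows but the matrix has ",
         ncol(states), " characters")
  }
  bad_stage <- !is.na(char_meta$stage) & !char_meta$stage %in% STAGE_LEVELS
  if (any(bad_stage)) {
    stop("unknown stage(s): ",
         paste(unique(char_meta$stage[bad_stage]), collapse = ", "))
  }
  bad_organ <- !is.na(char_meta$organ) & !char_meta$organ %in% ORGAN_LEVELS
  if (any(bad_organ)) {
    stop("unknown organ(s): ",
         paste(unique(char_meta$organ[bad_organ]), collapse = ", "))
  }
  # body part applies to adult characters only
  ok <- is.na(char_meta$stage) | is.na(char_meta$organ) |
    (char_meta$stage == "adult") == (char_meta$organ != "none")
  if (!all(ok)) {
    stop("organ must be 'none' exactly for non-adult characters; offending ",
         "char_id(s): ", paste(char_meta$char_id[!ok], collapse = ", "))
  }
  colnames(states) <- char_meta$char_id
  structure(list(states = states, taxa = taxa, char_meta = char_meta),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("<character_matrix> ", length(x$taxa), " taxa x ",
      ncol(x$states), " characters\n", sep = "")
  miss <- mean(is.na(x$states)) * 100
  cat(sprintf("  missing/inapplicable: %.1f%%\n", miss))
  if (!all(is.na(x$char_meta$stage))) {
    tb <- table(factor(x$char_meta$stage, levels = STAGE_LEVELS))
    cat("  stages:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) dim(x$states)

#' Number of distinct observed states per character
#'
#' Counts distinct non-missing state codes for each character.
#'
#' @param cm a [character_matrix()]
#' @return tibble with `char_id` and `n_states`
#' @export
state_counts <- function(cm) {
  stopifnot(inherits(cm, "character_matrix"))
  tibble::tibble(
    char_id = cm$char_meta$char_id,
    n_states = unname(apply(cm$states, 2,
                            function(col) length(unique(col[!is.na(col)]))))
  )
}

#' Recode the states of one character
#'
#' Applies an explicit old-state to new-state mapping to a single character,
#' optionally restricted to a subset of taxa. This supports coding overrides
#' where biological knowledge splits a statistically lumped state (e.g.
#' promoting the absence of a structure to its own state) or, with
#' `allow_merge = TRUE`, deliberately merges states.
#'
#' @param cm a [character_matrix()]
#' @param char_id character id to recode
#' @param rule named integer vector: `names(rule)` are old state codes,
#'   values are new codes. States absent from the rule are left unchanged.
#' @param taxa optional taxon labels to which the rule is restricted; other
#'   taxa keep their current code (used to split one state by a taxon
#'   predicate).
#' @param allow_merge set `TRUE` to permit a rule that maps two distinct old
#'   codes (or an old code and an untouched one) onto the same new code.
#' @return a new `character_matrix`
#' @export
recode_state <- function(cm, char_id, rule, taxa = NULL, allow_merge = FALSE) {
  stopifnot(inherits(cm, "character_matrix"))
  j <- match(char_id, cm$char_meta$char_id)
  if (is.na(j)) stop("unknown char_id: ", char_id)
  col <- cm$states[, j]
  old <- as.integer(names(rule))
  new <- as.integer(rule)
  observed <- sort(unique(col[!is.na(col)]))
  if (!all(old %in% observed)) {
    stop("rule domain contains unobserved state(s): ",
         paste(setdiff(old, observed), collapse = ", "))
  }
  rows <- if (is.null(taxa)) seq_along(col) else match(taxa, cm$taxa)
  if (anyNA(rows)) stop("unknown taxa in recode_state()")
  out <- col
  idx <- match(col[rows], old)
  hit <- !is.na(idx)
  out[rows[hit]] <- new[idx[hit]]
  n_before <- length(observed)
  n_after <- length(unique(out[!is.na(out)]))
  if (n_after < n_before && !allow_merge) {
    stop("recode rule merges states (", n_before, " -> ", n_after,
         "); pass allow_merge = TRUE if intended")
  }
  cm$states[, j] <- out
  cm
}
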