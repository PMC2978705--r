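#' Parse point-variant codes
#'
#' A point-variant code such as `"D4S"` means: the aspartate at (1-based)
#' position 4 of the lead is substituted with serine. The wild-type letter in
#' the code is validated against the lead sequence, which catches mislabeled
#' variant tables. Positions must fall in the randomized region (the fixed
#' C-terminal linker is never variable).
#'
#' @param codes Character vector of codes like `"D4S"`.
#' @param lead A [peptide()] (or sequence string) the codes refer to.
#' @return A tibble with columns `code`, `position`, `wild`, `sub`.
#' @examples
#' parse_variants("D4S", lead_peptide("TNF1"))
#' @export
parse_variants <- function(codes, lead) {
  lead <- as_peptide(lead)
  m <- regmatches(codes, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", codes))
  rows <- purrr::map2(codes, m, function(code, parts) {
    if (length(parts) != 4L) {
      abort(sprintf("Malformed variant code '%s' (expected <letter><position><letter>).", code))
    }
    pos <- as.integer(parts[3])
    wild <- toupper(parts[2])
    sub <- toupper(parts[4])
    if (pos < 1L || pos > randomized_length(lead)) {
      abort(sprintf(
        "Variant '%s': position %d outside the randomized region 1..%d of %s.",
        code, pos, randomized_length(lead), lead$name
      ))
    }
    lead_res <- substr(lead$residues, pos, pos)
    if (wild != lead_res) {
      abort(sprintf(
        "Variant '%s': lead %s has %s (not %s) at position %d — mislabeled variant table?",
        code, lead$name, lead_res, wild, pos
      ))
    }
    if (!sub %in% amino_acids()) {
      abort(sprintf("Variant '%s': non-canonical substitution '%s'.", code, sub))
    }
    tibble::tibble(code = toupper(code), position = pos, wild = wild, sub = sub)
  })
  dplyr::bind_rows(rows)
}

#' Format point-variant codes
#'
#' Inverse of [parse_variants()]: `format_variant(4, "D", "S")` is `"D4S"`.
#'
#' @param position 1-based position vector.
#' @param wild,sub One-letter codes.
#' @return Character vector of codes.
#' @export
format_variant <- function(position, wild, sub) {
  paste0(toupper(wild), as.integer(position), toupper(sub))
}

#' Apply a set of point variants to a lead sequence
#'
#' Validates the set (one variant per position, wild letters matching the
#' lead) and returns the edited peptide. The result's name records the edit,
#' e.g. `"TNF1+D4S+P5Y"`.
#'
#' @param lead A [peptide()] or sequence string.
#' @param codes Character vector of variant codes (may be empty).
#' @return A [peptide()] of the same length as the lead.
#' @examples
#' apply_variants(lead_peptide("TNF1"), c("D4S", "P5Y", "M7K", "S11K"))
#' @export
apply_variants <- function(lead, codes) {
  lead <- as_peptide(lead)
  if (length(codes) == 0L) return(lead)
  vs <- parse_variants(codes, lead)
  if (anyDuplicated(vs$position)) {
    dup <- vs$position[duplicated(vs$position)]
    abort(sprintf("Multiple variants at position(s) %s.", paste(unique(dup), collapse = ", ")))
  }
  chars <- strsplit(lead$residues, "")[[1]]
  chars[vs$position] <- vs$sub
  peptide(
    paste(chars, collapse = ""),
    name = paste(c(lead$name, vs$code), collapse = "+"),
    linker_length = lead$linker_length
  )
}

#' Enumerate a point-variant library
#'
#' Builds the single-substitution library over a substitution alphabet and a
#' set of randomized positions. In `exclude_identity` mode (the default)
#' substitutions equal to the lead residue are dropped, so the count is
#' `|positions| * |alphabet|` minus the number of positions whose lead
#' residue is in the alphabet; `include_identity` keeps them (identity
#' members reproduce the lead sequence and serve as in-library controls).
#'
#' @param lead A [peptide()].
#' @param alphabet Character vector of substitution letters (default the
#'   8-letter set Y, A, D, S, K, N, V, W used for the TNF1 scan).
#' @param positions 1-based positions to vary; default all randomized
#'   positions. Positions inside the fixed linker are an error.
#' @param mode `"exclude_identity"` or `"include_identity"`.
#' @return A tibble with columns `variant_code`, `sequence`, `position`,
#'   `wild`, `sub`, `mw_da`, `gravy`.
#' @examples
#' nrow(enumerate_variants(lead_peptide("TNF1"))) # 132
#' @export
enumerate_variants <- function(lead,
                               alphabet = c("Y", "A", "D", "S", "K", "N", "V", "W"),
                               positions = NULL,
                               mode = c("exclude_identity", "include_identity")) {
  lead <- as_peptide(lead)
  mode <- match.arg(mode)
  alphabet <- unique(toupper(alphabet))
  if (length(alphabet) == 0L) abort("`alphabet` must not be empty.")
  bad <- setdiff(alphabet, amino_acids())
  if (length(bad) > 0L) abort(sprintf("Non-canonical alphabet letter(s): %s", paste(bad, collapse = ", ")))
  if (is.null(positions)) positions <- seq_len(randomized_length(lead))
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > randomized_length(lead))) {
    abort(sprintf(
      "Library positions must lie in the randomized region 1..%d (the C-terminal linker is fixed).",
      randomized_length(lead)
    ))
  }
  grid <- tidyr::expand_grid(position = positions, sub = alphabet)
  grid$wild <- substring(lead$residues, grid$position, grid$position)
  if (mode == "exclude_identity") grid <- dplyr::filter(grid, .data$wild != .data$sub)
  chars <- strsplit(lead$residues, "")[[1]]
  grid$sequence <- purrr::map2_chr(grid$position, grid$sub, function(p, s) {
    ch <- chars
    ch[p] <- s
    paste(ch, collapse = "")
  })
  grid$variant_code <- format_variant(grid$position, grid$wild, grid$sub)
  out <- dplyr::select(grid, "variant_code", "sequence", "position", "wild", "sub")
  out$mw_da <- molecular_weight(out$sequence)
  out$gravy <- gravy(out$sequence)
  out
}
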