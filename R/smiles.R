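# SMILES tokenization, grammar parsing, validity, canonicalization and
# reactant-set comparison. The grammar parser is deliberately independent of
# OpenBabel: OB silently "repairs" some malformed strings (e.g. unbalanced
# parentheses), while model evaluation needs a strict notion of *grammatical*
# validity.

# atom-level token pattern: bracket atoms, two-letter halogens, organic-subset
# atoms, two-digit ring closures, digits, bonds, branches, dot
.SMI_TOKEN_RE <- paste0(
  "\\[[^\\[\\]]*\\]|Br|Cl|%[0-9]{2}|",
  "[BCNOSPFIbcnops*]|[0-9]|[-=#$:/\\\\.()+]"
)

.BRACKET_RE <- paste0(
  "^\\[[0-9]*(?:[A-Z][a-z]?|b|c|n|o|p|s|se|as|\\*)",
  "(?:@{1,2})?(?:H[0-9]*)?(?:[+-][0-9]*)?(?::[0-9]+)?\\]$"
)

#' Tokenize a SMILES string into atom-level tokens
#'
#' Splits a SMILES string into the token alphabet conventional for molecular
#' sequence models: bracket atoms (`[nH]`, `[O-]`, ...), the two-letter
#' halogens `Cl` and `Br`, organic-subset atoms, ring-closure digits and
#' two-digit `%NN` closures, bond and branch symbols, and the `.` molecule
#' separator -- each as a single token. Concatenating the returned tokens
#' reproduces the input exactly.
#'
#' @param s A single non-empty SMILES string.
#' @return Character vector of tokens whose concatenation equals `s`.
#' @examples
#' tokenize_smiles("Clc1ccccc1")
#' tokenize_smiles("C[nH]1cccc1")
#' @export
tokenize_smiles <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    stop("tokenize_smiles() expects a single non-empty string")
  # bracket balance first: an unterminated '[' can otherwise be half-consumed
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (ch in chars) {
    if (ch == "[") {
      depth <- depth + 1L
      if (depth > 1L) stop("unbalanced '[' in SMILES: ", s)
    } else if (ch == "]") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ']' in SMILES: ", s)
    }
  }
  if (depth != 0L) stop("unbalanced '[' in SMILES: ", s)
  m <- gregexpr(.SMI_TOKEN_RE, s, perl = TRUE)[[1]]
  toks <- regmatches(s, gregexpr(.SMI_TOKEN_RE, s, perl = TRUE))[[1]]
  if (paste(toks, collapse = "") != s) {
    covered <- rep(FALSE, nchar(s))
    for (i in seq_along(m)) {
      if (m[i] > 0)
        covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
    }
    bad <- which(!covered)[1]
    stop(sprintf("untokenizable character '%s' at position %d in SMILES: %s",
                 substr(s, bad, bad), bad, s))
  }
  toks
}

#' Reassemble tokens into a SMILES string
#'
#' Inverse of [tokenize_smiles()]: plain concatenation.
#'
#' @param tokens Character vector of tokens.
#' @return A single string.
#' @export
detokenize_smiles <- function(tokens) paste(tokens, collapse = "")

# parse a single SMILES string into a molecular graph, or stop() with a
# grammar error. Returns list(atoms = data.frame(element, aromatic, charge),
# bonds = data.frame(a, b, order)) where order uses 1.5 for aromatic bonds.
parse_smiles <- function(s) {
  if (grepl("[[:space:]]", s)) stop("whitespace in SMILES")
  toks <- tokenize_smiles(s)
  bond_order <- c("-" = 1, "=" = 2, "#" = 3, "$" = 4, ":" = 1.5,
                  "/" = 1, "\\" = 1)

  element <- character(0); aromatic <- logical(0); charge <- integer(0)
  bond_a <- integer(0); bond_b <- integer(0); bond_o <- numeric(0)

  prev <- NA_integer_       # atom awaiting the next bond
  stack <- integer(0)       # branch return points
  pending <- NA_real_       # explicit bond awaiting its right-hand atom
  rings <- list()           # open ring closures: label -> list(atom, order)
  last <- "start"           # last token class, for adjacency rules

  add_atom <- function(el, arom, chg) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    length(element)
  }
  add_bond <- function(a, b, o) {
    if (a == b) stop("ring bond to self")
    if (any((bond_a == a & bond_b == b) | (bond_a == b & bond_b == a)))
      stop("duplicate bond between atoms ", a, " and ", b)
    bond_a[length(bond_a) + 1L] <<- a
    bond_b[length(bond_b) + 1L] <<- b
    bond_o[length(bond_o) + 1L] <<- o
  }

  for (tk in toks) {
    if (grepl("^\\[", tk)) {
      if (!grepl(.BRACKET_RE, tk)) stop("malformed bracket atom: ", tk)
      core <- sub("^\\[[0-9]*", "", tk)
      el <- regmatches(core, regexpr("^(?:[A-Z][a-z]?|b|c|n|o|p|s|se|as|\\*)",
                                     core))
      chg <- 0L
      cm <- regmatches(tk, regexpr("[+-][0-9]*(?=(:[0-9]+)?\\]$)", tk,
                                   perl = TRUE))
      if (length(cm) == 1L && nzchar(cm)) {
        sign <- if (substr(cm, 1, 1) == "+") 1L else -1L
        num <- substr(cm, 2, nchar(cm))
        chg <- sign * (if (nzchar(num)) as.integer(num) else 1L)
      }
      arom <- el %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      a <- add_atom(toupper(substr(el, 1, 1)) |>
                      paste0(substr(el, 2, nchar(el))), arom, chg)
      if (!is.na(prev)) {
        o <- if (!is.na(pending)) pending
             else if (aromatic[prev] && arom) 1.5 else 1
        add_bond(prev, a, o)
      } else if (!is.na(pending)) stop("bond with no preceding atom")
      prev <- a; pending <- NA_real_; last <- "atom"
    } else if (grepl("^(Br|Cl|[BCNOSPFIbcnops*])$", tk)) {
      arom <- tk %in% c("b", "c", "n", "o", "p", "s")
      el <- if (arom) toupper(tk) else tk
      a <- add_atom(el, arom, 0L)
      if (!is.na(prev)) {
        o <- if (!is.na(pending)) pending
             else if (aromatic[prev] && arom) 1.5 else 1
        add_bond(prev, a, o)
      } else if (!is.na(pending)) stop("bond with no preceding atom")
      prev <- a; pending <- NA_real_; last <- "atom"
    } else if (grepl("^[0-9]$|^%[0-9]{2}$", tk)) {
      if (is.na(prev)) stop("ring closure with no preceding atom")
      if (!(last %in% c("atom", "ring", "bond")))
        stop("ring closure may not follow '", last, "'")
      lab <- sub("^%", "", tk)
      if (!is.null(rings[[lab]])) {
        op <- rings[[lab]]
        o <- if (!is.na(pending) && !is.na(op$order)) {
          if (pending != op$order) stop("conflicting ring-bond orders")
          pending
        } else if (!is.na(pending)) pending
          else if (!is.na(op$order)) op$order
          else if (aromatic[prev] && aromatic[op$atom]) 1.5 else 1
        add_bond(op$atom, prev, o)
        rings[[lab]] <- NULL
      } else {
        rings[[lab]] <- list(atom = prev, order = pending)
      }
      pending <- NA_real_; last <- "ring"
    } else if (tk %in% names(bond_order)) {
      if (!is.na(pending)) stop("two consecutive bond symbols")
      if (!(last %in% c("atom", "ring", "(")))
        stop("bond in invalid position")
      pending <- bond_order[[tk]]; last <- "bond"
    } else if (tk == "(") {
      if (!(last %in% c("atom", "ring"))) stop("branch in invalid position")
      stack <- c(stack, prev); last <- "("
    } else if (tk == ")") {
      if (length(stack) == 0L) stop("unbalanced ')'")
      if (!(last %in% c("atom", "ring"))) stop("branch ends after '", last, "'")
      if (!is.na(pending)) stop("dangling bond before ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      last <- "atom"
    } else if (tk == ".") {
      if (length(stack) > 0L) stop("'.' inside a branch")
      if (!(last %in% c("atom", "ring"))) stop("'.' after '", last, "'")
      if (!is.na(pending)) stop("dangling bond before '.'")
      prev <- NA_integer_; last <- "start"
    } else if (tk == "+") {
      stop("'+' outside a bracket atom")
    } else stop("unexpected token: ", tk)
  }
  if (length(stack) > 0L) stop("unbalanced '('")
  if (!is.na(pending)) stop("dangling bond at end of SMILES")
  if (length(rings) > 0L)
    stop("unclosed ring bond(s): ", paste(names(rings), collapse = ", "))
  if (!(last %in% c("atom", "ring"))) stop("SMILES ends after '", last, "'")
  list(atoms = data.frame(element = element, aromatic = aromatic,
                          charge = charge, stringsAsFactors = FALSE),
       bonds = data.frame(a = bond_a, b = bond_b, order = bond_o))
}

#' Test whether a string is grammatically valid SMILES
#'
#' A string is valid when it parses under the package's SMILES grammar:
#' balanced brackets, branches and ring-bond labels, well-formed bracket
#' atoms, bonds in legal positions, and every dot-separated component
#' non-empty. This is *grammatical* validity -- the criterion under which
#' predicted strings are scored as parseable or not -- and makes no claim
#' about chemical sanity (valence, aromaticity).
#'
#' Never raises on bad input; malformed strings simply return `FALSE`.
#'
#' @param s Character vector of candidate SMILES strings.
#' @return Logical vector, one entry per input string.
#' @examples
#' is_valid_smiles(c("c1ccccc1", "C1CC", "C((C"))
#' @export
is_valid_smiles <- function(s) {
  vapply(s, function(x) {
    if (is.na(x) || !nzchar(x)) return(FALSE)
    !inherits(tryCatch(parse_smiles(x), error = function(e) e), "error")
  }, logical(1), USE.NAMES = FALSE)
}

# one OpenBabel round trip for a vector of grammatically valid SMILES; the
# index is carried through as a molecule title so that strings OB cannot
# parse chemically come back as NA instead of misaligning the batch
.ob_canonical <- function(s) {
  if (length(s) == 0L) return(character(0))
  inp <- paste0(s, " m", seq_along(s), collapse = "\n")
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(inp, "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  res <- rep(NA_character_, length(s))
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2L && grepl("^m[0-9]+$", parts[2])) {
      i <- as.integer(sub("^m", "", parts[2]))
      if (nzchar(parts[1])) res[i] <- parts[1]
    }
  }
  res
}

#' Canonicalize SMILES strings
#'
#' Maps every SMILES of the same molecular graph to one unique string
#' (OpenBabel canonical form, via ChemmineOB), which is what makes
#' exact-match accuracy well defined. Idempotent: canonical strings map to
#' themselves.
#'
#' @param s Character vector of grammatically valid SMILES.
#' @return Character vector of canonical SMILES.
#' @seealso [reactant_set_match()] for order-insensitive comparison.
#' @examples
#' canonicalize("OCC") == canonicalize("CCO")
#' @export
canonicalize <- function(s) {
  ok <- is_valid_smiles(s)
  if (!all(ok))
    stop("cannot canonicalize grammatically invalid SMILES: ",
         paste(s[!ok], collapse = ", "))
  res <- .ob_canonical(s)
  if (anyNA(res))
    stop("chemically unparseable SMILES: ",
         paste(s[is.na(res)], collapse = ", "))
  res
}

# canonical multiset of the '.'-separated components of each string, or NA
# where the string is grammatically or chemically unparseable. One OB call
# for the whole vector.
.canonical_multisets <- function(s) {
  comps <- strsplit(s, ".", fixed = TRUE)
  valid <- is_valid_smiles(s)
  flat <- unlist(comps[valid], use.names = FALSE)
  uniq <- unique(flat)
  canon <- if (length(uniq)) .ob_canonical(uniq) else character(0)
  names(canon) <- uniq
  out <- vector("list", length(s))
  for (i in seq_along(s)) {
    if (!valid[i]) next
    cc <- canon[comps[[i]]]
    if (!anyNA(cc)) out[[i]] <- sort(unname(cc))
  }
  out
}

#' Compare a predicted reactant set against the ground truth
#'
#' Both arguments are dot-separated multi-molecule SMILES strings. The match
#' is `TRUE` iff both parse and their canonical molecule *multisets* are
#' equal -- order-insensitive, but a duplicated reactant must be predicted
#' the right number of times. A grammatically or chemically unparseable
#' prediction never matches.
#'
#' @param predicted,truth Character vectors (recycled to common length) of
#'   dot-separated SMILES strings.
#' @return Logical vector.
#' @examples
#' reactant_set_match("CCO.CC(=O)O", "CC(=O)O.OCC")  # TRUE
#' reactant_set_match("CCO", "CCO.CC(=O)O")          # FALSE
#' @export
reactant_set_match <- function(predicted, truth) {
  n <- max(length(predicted), length(truth))
  predicted <- rep_len(predicted, n); truth <- rep_len(truth, n)
  mp <- .canonical_multisets(predicted)
  mt <- .canonical_multisets(truth)
  vapply(seq_len(n), function(i) {
    !is.null(mp[[i]]) && !is.null(mt[[i]]) && identical(mp[[i]], mt[[i]])
  }, logical(1))
}
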