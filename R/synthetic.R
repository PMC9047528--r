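# Template-based synthetic retrosynthesis data. Fragments are spliced into
# product/reactant patterns by plain string substitution at marked slots, so
# every generated record is auditable by eye and parseable by construction.
# The five default templates mirror common medicinal-chemistry families
# (ester formation, SN2 etherification, Boc protection, amide condensation,
# aryl-aryl coupling) so that the failure-category machinery is exercised on
# the same motif vocabulary (Boc, CF3, tBu, rings) that real corpora show.

#' Construct a reaction template
#'
#' @param template_id Short string id.
#' @param class_id Reaction class slot (1-10).
#' @param product Product pattern, with fragment slots written `{NAME}`.
#' @param reactants Character vector of reactant patterns (fixed strings,
#'   e.g. a reagent, are allowed).
#' @param slots Named character vector: slot name -> fragment-library entry.
#' @return A list of class `reaction_template`.
#' @export
reaction_template <- function(template_id, class_id, product, reactants,
                              slots) {
  in_prod <- vapply(names(slots), function(s)
    grepl(paste0("{", s, "}"), product, fixed = TRUE), logical(1))
  for (s in names(slots)[!in_prod]) {
    used <- any(grepl(paste0("{", s, "}"), reactants, fixed = TRUE))
    if (used)
      stop("slot ", s, " appears in reactants but not in the product; ",
           "only fixed leaving groups may be product-absent")
  }
  structure(list(template_id = template_id, class_id = as.integer(class_id),
                 product = product, reactants = reactants, slots = slots),
            class = "reaction_template")
}

#' Default fragment library
#'
#' Named fragment alphabets with positional attachment conventions: a slot
#' at the start of a pattern splices at the fragment's last atom, a slot
#' after other atoms splices at its first atom. Every fragment yields valid
#' SMILES in every template that declares its alphabet. tBu, CF3 and
#' Boc-bearing fragments are included on purpose.
#'
#' @return Named list of character vectors.
#' @export
default_fragments <- function() {
  list(
    alkyl = c("C", "CC", "CCC", "CCCC", "CC(C)C", "CC(C)(C)C", "CCOCC",
              "COC", "Cc1ccccc1", "CCc1ccccc1"),
    acyl = c("CC(=O)", "CCC(=O)", "CCCC(=O)", "CC(C)C(=O)", "CC(C)(C)C(=O)",
             "FC(F)(F)C(=O)", "COCC(=O)", "OCC(=O)", "c1ccccc1C(=O)",
             "Cc1ccccc1C(=O)", "Clc1ccccc1C(=O)"),
    aryl_a = c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "COc1ccccc1",
               "Clc1ccccc1", "Fc1ccccc1", "FC(F)(F)c1ccccc1",
               "CC(C)c1ccccc1", "CC(C)(C)c1ccccc1"),
    aryl_b = c("c1ccccc1", "c1ccc(C)cc1", "c1ccc(CC)cc1", "c1ccc(OC)cc1",
               "c1ccc(F)cc1", "c1ccc(C(C)(C)C)cc1", "c1ccncc1",
               "c1ccc(Cl)cc1", "c1ccc(C(F)(F)F)cc1", "c1ccoc1"))
}

#' Default reaction templates
#'
#' Five two-slot templates across reaction classes 1-5 (the remaining class
#' ids stay empty unless extra templates are configured):
#' ester formation (acid + alcohol), SN2 etherification (alkyl bromide +
#' phenol), Boc protection of a secondary amine (amine + Boc anhydride),
#' amide condensation (acid + amine), and Suzuki aryl-aryl coupling (aryl
#' bromide + boronic acid).
#'
#' @return List of `reaction_template`s.
#' @export
default_templates <- function() {
  list(
    reaction_template("ester_formation", 1L,
                      "{ACYL}O{ALKYL}",
                      c("{ACYL}O", "O{ALKYL}"),
                      c(ACYL = "acyl", ALKYL = "alkyl")),
    reaction_template("sn2_etherification", 2L,
                      "{ALKYL}O{ARYL}",
                      c("O{ARYL}", "{ALKYL}Br"),
                      c(ALKYL = "alkyl", ARYL = "aryl_b")),
    reaction_template("boc_protection", 3L,
                      "{ALKYLA}N(C(=O)OC(C)(C)C){ALKYLB}",
                      c("{ALKYLA}N{ALKYLB}",
                        "CC(C)(C)OC(=O)OC(=O)OC(C)(C)C"),
                      c(ALKYLA = "alkyl", ALKYLB = "alkyl")),
    reaction_template("amide_condensation", 4L,
                      "{ACYL}N{ALKYL}",
                      c("{ACYL}O", "N{ALKYL}"),
                      c(ACYL = "acyl", ALKYL = "alkyl")),
    reaction_template("suzuki_coupling", 5L,
                      "{ARYLA}{ARYLB}",
                      c("{ARYLA}Br", "OB(O){ARYLB}"),
                      c(ARYLA = "aryl_a", ARYLB = "aryl_b")))
}

#' Instantiate a template with a slot assignment
#'
#' Deterministic string substitution of fragments into the product and
#' reactant patterns; the resulting record is checked to be grammatically
#' valid on both sides.
#'
#' @param template A `reaction_template`.
#' @param assignment Named character vector slot -> fragment SMILES; every
#'   fragment must belong to the slot's declared alphabet.
#' @param library Fragment library the template draws from.
#' @param record_id Id for the new record.
#' @return A `reaction_record`.
#' @examples
#' tpl <- default_templates()[[1]]
#' apply_template(tpl, c(ACYL = "CC(=O)", ALKYL = "C"))
#' @export
apply_template <- function(template, assignment,
                           library = default_fragments(),
                           record_id = template$template_id) {
  miss <- setdiff(names(template$slots), names(assignment))
  if (length(miss))
    stop("assignment misses slot(s): ", paste(miss, collapse = ", "))
  for (s in names(template$slots)) {
    alphabet <- library[[template$slots[[s]]]]
    if (!assignment[[s]] %in% alphabet)
      stop("fragment '", assignment[[s]], "' not in alphabet '",
           template$slots[[s]], "' for slot ", s)
  }
  fill <- function(pattern) {
    for (s in names(template$slots))
      pattern <- gsub(paste0("{", s, "}"), assignment[[s]], pattern,
                      fixed = TRUE)
    pattern
  }
  product <- fill(template$product)
  reactants <- vapply(template$reactants, fill, character(1),
                      USE.NAMES = FALSE)
  ok <- is_valid_smiles(c(product, reactants))
  if (!all(ok))
    stop("template instantiation produced invalid SMILES: ",
         paste(c(product, reactants)[!ok], collapse = ", "))
  reaction_record(record_id, template$class_id, reactants, product)
}

#' Generate a synthetic retrosynthesis dataset
#'
#' Takes the full cross-product of slot assignments for every template,
#' shuffles it with a platform-stable permutation, and holds out whole slot
#' *combinations* -- never individual fragments -- for the validation and
#' test splits, so that held-out evaluation requires recombining fragments
#' the model has seen only in other contexts, not memorization. If removing
#' a combination would remove a fragment's last occurrence from the training
#' split, that combination is kept in train and the next one is held out
#' instead.
#'
#' @param templates List of `reaction_template`s.
#' @param library Fragment library.
#' @param seed Integer seed (same seed, same dataset, byte for byte).
#' @param heldout_fraction Fraction of each template's combinations held out
#'   for test, and again for validation. Must be < 1 (jointly < 1 after
#'   doubling).
#' @return A `dataset_split`; attribute `class_counts` reports the class
#'   balance of the training split.
#' @export
generate_dataset <- function(templates = default_templates(),
                             library = default_fragments(), seed = 1L,
                             heldout_fraction = 0.1) {
  if (length(templates) == 0L) stop("templates must be non-empty")
  if (heldout_fraction >= 1 || 2 * heldout_fraction >= 1)
    stop("heldout_fraction too large (train split would be empty)")
  train <- list(); val <- list(); test <- list()
  for (ti in seq_along(templates)) {
    tpl <- templates[[ti]]
    alphabets <- lapply(tpl$slots, function(lib) library[[lib]])
    grid <- expand.grid(alphabets, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    n <- nrow(grid)
    recs <- lapply(seq_len(n), function(i) {
      assignment <- vapply(names(tpl$slots), function(s) grid[[s]][i],
                           character(1))
      apply_template(tpl, assignment, library,
                     record_id = sprintf("%s-%03d", tpl$template_id, i))
    })
    perm <- .fisher_yates(n, seed + ti)
    n_test <- floor(n * heldout_fraction)
    n_val <- floor(n * heldout_fraction)
    take_test <- perm[seq_len(n_test)]
    take_val <- perm[n_test + seq_len(n_val)]
    take_train <- perm[-seq_len(n_test + n_val)]
    # fragment-coverage guard: every fragment must survive in train
    for (s in names(tpl$slots)) {
      frag_train <- unique(grid[[s]][take_train])
      missing <- setdiff(unique(grid[[s]]), frag_train)
      for (fr in missing) {
        held <- c(take_test, take_val)
        idx <- held[grid[[s]][held] == fr][1]
        swap <- take_train[1]
        if (idx %in% take_test)
          take_test[take_test == idx] <- swap
        else take_val[take_val == idx] <- swap
        take_train <- c(take_train[-1], idx)
      }
    }
    train <- c(train, recs[sort(take_train)])
    val <- c(val, recs[sort(take_val)])
    test <- c(test, recs[sort(take_test)])
  }
  split <- structure(list(train = train, validation = val, test = test,
                          seed = as.integer(seed),
                          fractions = c(1 - 2 * heldout_fraction,
                                        heldout_fraction, heldout_fraction)),
                     class = "dataset_split")
  attr(split, "class_counts") <-
    table(vapply(train, `[[`, integer(1), "class_id"))
  split
}

#' Corrupt a valid SMILES into a grammatically invalid string
#'
#' Applies one random corruption -- deleting a ring-closure digit,
#' unbalancing a parenthesis, or truncating a bracket atom -- and verifies
#' the result fails [is_valid_smiles()]; up to 10 corruptions are tried
#' before giving up. Used to plant known-invalid strings in validity tests.
#'
#' @param s A valid SMILES string.
#' @param seed Integer seed.
#' @return An invalid string.
#' @export
mutate_to_invalid <- function(s, seed = 1L) {
  if (!is_valid_smiles(s)) stop("input must be valid SMILES")
  rng <- .lcg_stream(seed)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (attempt in seq_len(10L)) {
    moves <- list()
    digits <- which(grepl("[0-9]", chars))
    if (length(digits))
      moves$ring <- function() {
        i <- digits[1L + rng() %% length(digits)]
        paste(chars[-i], collapse = "")
      }
    parens <- which(chars == "(")
    moves$paren <- function() {
      if (length(parens)) {
        i <- parens[1L + rng() %% length(parens)]
        paste(c(chars[seq_len(i)], "(", chars[-seq_len(i)]), collapse = "")
      } else {
        i <- 1L + rng() %% length(chars)
        paste(c(chars[seq_len(i)], "(", chars[-seq_len(i)]), collapse = "")
      }
    }
    closes <- which(chars == "]")
    if (length(closes))
      moves$bracket <- function() paste(chars[-closes[1]], collapse = "")
    pick <- moves[[1L + rng() %% length(moves)]]
    out <- pick()
    if (nzchar(out) && !is_valid_smiles(out)) return(out)
  }
  stop("could not produce an invalid mutation of: ", s)
}
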