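# Ring perception (smallest set of smallest rings) and substructure
# matching on the package's own SMILES molecular graph. Used to categorize
# the molecules on which predictions fail: complex ring systems (fused,
# spiro, bridged) and quaternary-carbon motifs (Boc, CF3, tBu).

# adjacency list from a parse_smiles() graph
.adjacency <- function(graph) {
  n <- nrow(graph$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$a[i]; b <- graph$bonds$b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# BFS shortest path from u to v avoiding one edge; returns atom path or NULL
.bfs_path <- function(adj, u, v, skip_a, skip_b) {
  n <- length(adj)
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  queue <- u; seen[u] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur == v) break
    for (nb in adj[[cur]]) {
      if ((cur == skip_a && nb == skip_b) || (cur == skip_b && nb == skip_a))
        next
      if (!seen[nb]) {
        seen[nb] <- TRUE; prev[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  if (!seen[v]) return(NULL)
  path <- v
  while (path[1] != u) path <- c(prev[path[1]], path)
  path
}

# smallest set of smallest rings: candidate cycles are, for every edge, the
# shortest cycle through it; a greedy pass ordered by ring size keeps cycles
# that are independent in the GF(2) edge space until the cycle-space
# dimension (E - V + components) is reached.
.sssr <- function(graph) {
  nb <- nrow(graph$bonds); na <- nrow(graph$atoms)
  if (nb == 0L) return(list())
  adj <- .adjacency(graph)
  comp <- 0L; seen <- rep(FALSE, na)
  for (s in seq_len(na)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (x in adj[[cur]]) if (!seen[x]) { seen[x] <- TRUE; queue <- c(queue, x) }
    }
  }
  dim_needed <- nb - na + comp
  if (dim_needed <= 0L) return(list())

  edge_id <- function(a, b) which((graph$bonds$a == a & graph$bonds$b == b) |
                                    (graph$bonds$a == b & graph$bonds$b == a))
  cand <- list()
  for (e in seq_len(nb)) {
    a <- graph$bonds$a[e]; b <- graph$bonds$b[e]
    path <- .bfs_path(adj, a, b, a, b)
    if (is.null(path)) next
    atoms <- path
    edges <- c(e, vapply(seq_len(length(path) - 1L), function(i)
      edge_id(path[i], path[i + 1L]), integer(1)))
    key <- paste(sort(edges), collapse = ",")
    if (!key %in% vapply(cand, `[[`, character(1), "key"))
      cand[[length(cand) + 1L]] <- list(atoms = sort(atoms),
                                        edges = sort(edges), key = key)
  }
  cand <- cand[order(lengths(lapply(cand, `[[`, "atoms")),
                     vapply(cand, `[[`, character(1), "key"))]

  basis <- matrix(0L, 0L, nb)
  rings <- list()
  for (r in cand) {
    if (length(rings) == dim_needed) break
    vec <- integer(nb); vec[r$edges] <- 1L
    # GF(2) elimination against the accepted basis
    red <- vec
    if (nrow(basis)) {
      for (i in seq_len(nrow(basis))) {
        piv <- which(basis[i, ] == 1L)[1]
        if (red[piv] == 1L) red <- (red + basis[i, ]) %% 2L
      }
    }
    if (any(red == 1L)) {
      basis <- rbind(basis, red)
      rings[[length(rings) + 1L]] <- r
    }
  }
  rings
}

#' Classify the ring system of a molecule
#'
#' Perceives the smallest set of smallest rings and classifies the molecule
#' by how its rings share atoms: two rings sharing exactly one atom make it
#' spiro, sharing exactly one bond fused, and sharing two or more atoms that
#' are not all on one shared bond bridged. When several relations coexist
#' the precedence is bridged > spiro > fused. Complex ring systems of these
#' kinds are exactly the substructures on which sequence models tend to emit
#' ungrammatical SMILES.
#'
#' @param s A single valid SMILES string.
#' @return One of `"acyclic"`, `"simple-ring"`, `"fused"`, `"spiro"`,
#'   `"bridged"`.
#' @examples
#' classify_ring_system("C1CCC2(CC1)CCCC2")   # spiro
#' classify_ring_system("C1CC2CCC1C2")        # bridged
#' classify_ring_system("C1CCC2CCCCC2C1")     # fused
#' @export
classify_ring_system <- function(s) {
  if (length(s) != 1L) stop("classify_ring_system() takes a single SMILES")
  graph <- tryCatch(parse_smiles(s), error = function(e)
    stop("invalid SMILES: ", s, " (", conditionMessage(e), ")"))
  rings <- .sssr(graph)
  if (length(rings) == 0L) return("acyclic")
  if (length(rings) == 1L) return("simple-ring")
  has_spiro <- FALSE; has_fused <- FALSE; has_bridged <- FALSE
  for (i in seq_len(length(rings) - 1L)) {
    for (j in (i + 1L):length(rings)) {
      sa <- length(intersect(rings[[i]]$atoms, rings[[j]]$atoms))
      sb <- length(intersect(rings[[i]]$edges, rings[[j]]$edges))
      if (sa == 0L) next
      if (sa == 1L) has_spiro <- TRUE
      else if (sa == 2L && sb == 1L) has_fused <- TRUE
      else has_bridged <- TRUE
    }
  }
  if (has_bridged) return("bridged")
  if (has_spiro) return("spiro")
  if (has_fused) return("fused")
  "simple-ring"
}

# subgraph matching: every pattern atom maps to a distinct target atom with
# equal element and aromaticity, and every pattern bond exists in the target
# with the same order (extra target bonds are allowed).
.match_subgraph <- function(target, pattern) {
  nt <- nrow(target$atoms); np <- nrow(pattern$atoms)
  if (np > nt) return(FALSE)
  tadj <- .adjacency(target); padj <- .adjacency(pattern)
  t_ord <- function(a, b) {
    i <- which((target$bonds$a == a & target$bonds$b == b) |
                 (target$bonds$a == b & target$bonds$b == a))
    target$bonds$order[i[1]]
  }
  p_ord <- function(a, b) {
    i <- which((pattern$bonds$a == a & pattern$bonds$b == b) |
                 (pattern$bonds$a == b & pattern$bonds$b == a))
    pattern$bonds$order[i[1]]
  }
  # order pattern atoms so each (after the first) touches an earlier one
  order_p <- 1L
  while (length(order_p) < np) {
    nxt <- setdiff(unlist(padj[order_p]), order_p)
    if (length(nxt) == 0L) nxt <- setdiff(seq_len(np), order_p)[1]
    order_p <- c(order_p, nxt[1])
  }
  compat <- function(pa, ta) {
    if (length(tadj[[ta]]) < length(padj[[pa]])) return(FALSE)
    if (pattern$atoms$element[pa] == "*") return(TRUE)  # wildcard atom
    target$atoms$element[ta] == pattern$atoms$element[pa] &&
      target$atoms$aromatic[ta] == pattern$atoms$aromatic[pa]
  }

  assign_next <- function(map) {
    k <- sum(!is.na(map))
    if (k == np) return(TRUE)
    pa <- order_p[k + 1L]
    anchors <- intersect(padj[[pa]], order_p[seq_len(k)])
    cands <- if (length(anchors)) {
      Reduce(intersect, lapply(anchors, function(an) tadj[[map[an]]]))
    } else seq_len(nt)
    cands <- setdiff(cands, map[!is.na(map)])
    for (ta in cands) {
      if (!compat(pa, ta)) next
      ok <- TRUE
      for (an in anchors) {
        if (!isTRUE(all.equal(p_ord(pa, an), t_ord(ta, map[an])))) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      map[pa] <- ta
      if (assign_next(map)) return(TRUE)
      map[pa] <- NA_integer_
    }
    FALSE
  }
  assign_next(rep(NA_integer_, np))
}

#' Test whether a molecule contains a substructure
#'
#' Plain subgraph matching on elements, aromaticity and bond orders, using
#' patterns written as SMILES. Sufficient for the motif registry shipped
#' with the package (no general SMARTS logic).
#'
#' @param s Molecule SMILES.
#' @param pattern Substructure SMILES.
#' @return `TRUE` or `FALSE`.
#' @examples
#' has_substructure("CC(C)(C)OC(=O)NC", "CC(C)(C)OC(=O)N")  # Boc
#' @export
has_substructure <- function(s, pattern) {
  .match_subgraph(parse_smiles(s), parse_smiles(pattern))
}

#' The failure-category substructure registry
#'
#' Named motifs whose presence in a ground-truth molecule categorizes a
#' failed prediction: the quaternary-carbon protecting/activating groups
#' (Boc as tert-butyl carbamate, trifluoromethyl, tert-butyl) and the
#' complex ring classes from [classify_ring_system()]. Boc takes precedence
#' over tBu, so a tert-butyl carbamate does not additionally count as plain
#' tert-butyl.
#'
#' @return data.frame with columns `category`, `kind` (`"pattern"` or
#'   `"ring"`), `value`, `precedence_over` (comma-separated categories this
#'   one suppresses).
#' @export
default_failure_registry <- function() {
  data.frame(
    category = c("R-Boc", "R-CF3", "R-tBu", "R-fused", "R-spiro", "R-bridged"),
    kind = c("pattern", "pattern", "pattern", "ring", "ring", "ring"),
    value = c("CC(C)(C)OC(=O)N", "C(F)(F)F", "CC(C)(C)*",
              "fused", "spiro", "bridged"),
    precedence_over = c("R-tBu", "", "", "", "", ""),
    stringsAsFactors = FALSE)
}
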