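# Minimal SMILES parser covering the organic subset, bracket atoms,
# branches, ring-closure digits (incl. %nn) and aromatic lower-case atoms.
# Stereo markers (/ \ @) are accepted and ignored: nothing downstream is
# stereo-aware. This is deliberately NOT a general cheminformatics toolkit;
# it supports exactly what the descriptor and fingerprint layers need:
# element counts, implicit hydrogens, bond orders, aromaticity and rings.

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
# standard valence alternatives per element (smallest >= bond sum wins)
.default_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles A SMILES string.
#' @param id Optional compound id carried on parse errors.
#' @return An object of class `mcl_mol`: a list with `atoms` (data frame:
#'   `element`, `aromatic`, `charge`, `h` implicit+explicit hydrogen count,
#'   `in_ring`, `in_ring3`) and `bonds` (data frame: `a1`, `a2`, `order`,
#'   `aromatic`).
#' @examples
#' mol <- parse_smiles("CCO")
#' mol$atoms$element
#' @export
parse_smiles <- function(smiles, id = NULL) {
  check_that(is.character(smiles) && length(smiles) == 1L && nzchar(smiles),
             "parse", "SMILES must be a non-empty string", id = id)
  perr <- function(msg) {
    mcl_stop("parse", sprintf("SMILES parse error%s in %s: %s",
                              if (is.null(id)) "" else paste0(" [id ", id, "]"),
                              dQuote(smiles), msg), id = id)
  }

  el <- character(); arom <- logical(); chg <- integer(); exh <- integer()
  bracket_flag <- logical()
  b1 <- integer(); b2 <- integer(); bord <- numeric(); barom <- logical()

  n <- 0L                      # atoms so far
  prev <- NA_integer_          # attachment atom
  stack <- integer()           # branch stack
  pend_bond <- NA_character_   # explicit bond symbol awaiting next atom
  rings <- list()              # open ring closures: num -> c(atom, bondsym)

  add_atom <- function(sym, aromatic, charge, hcount) {
    n <<- n + 1L
    el[n] <<- sym; arom[n] <<- aromatic
    chg[n] <<- charge; exh[n] <<- hcount
    n
  }
  add_bond <- function(a, b, sym) {
    if (is.na(a)) return(invisible(NULL))
    aromatic <- FALSE
    if (is.na(sym)) {
      if (arom[a] && arom[b]) { aromatic <- TRUE; ord <- 1 } else ord <- 1
    } else {
      ord <- switch(sym, "-" = 1, "=" = 2, "#" = 3, "$" = 4,
                    ":" = 1, "/" = 1, "\\" = 1,
                    perr(paste("unknown bond symbol", sym)))
      if (sym == ":") aromatic <- TRUE
    }
    b1[length(b1) + 1L] <<- a; b2[length(b2) + 1L] <<- b
    bord[length(bord) + 1L] <<- ord
    barom[length(barom) + 1L] <<- aromatic
    invisible(NULL)
  }
  connect <- function(at) {
    add_bond(prev, at, pend_bond)
    pend_bond <<- NA_character_
    prev <<- at
  }
  ring_event <- function(num) {
    key <- as.character(num)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, bond = pend_bond)
      pend_bond <<- NA_character_
    } else {
      open <- rings[[key]]
      sym <- if (!is.na(open$bond)) open$bond else pend_bond
      add_bond(open$atom, prev, sym)
      pend_bond <<- NA_character_
      rings[[key]] <<- NULL
    }
  }

  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  i <- 1L; len <- length(chars)
  while (i <= len) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= len && chars[j] != "]") j <- j + 1L
      if (j > len) perr("unclosed bracket atom")
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{0,2}|@TH[12]|@AL[12])(H[0-9]*)?(\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) perr(paste("bad bracket atom", dQuote(body)))
      sym <- m[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      symup <- if (aromatic) {
        paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      } else sym
      hs <- m[5]
      hcount <- if (is.na(hs) || hs == "") 0L
        else if (hs == "H") 1L else as.integer(substring(hs, 2))
      cs <- m[6]
      charge <- if (is.na(cs) || cs == "") 0L
        else if (grepl("^[+-][0-9]+$", cs)) as.integer(cs)
        else nchar(cs) * (if (substr(cs, 1, 1) == "+") 1L else -1L)
      if (symup == "H") {
        # explicit hydrogen atom: fold into the attachment atom
        if (is.na(prev)) perr("leading explicit [H] not supported")
        exh[prev] <- exh[prev] + 1L
        pend_bond <- NA_character_
        i <- j + 1L
        next
      }
      at <- add_atom(symup, aromatic, charge, hcount)
      bracket_flag[at] <- TRUE
      connect(at)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < len && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      at <- add_atom(paste0(ch, chars[i + 1L]), FALSE, 0L, NA_integer_)
      bracket_flag[at] <- FALSE
      connect(at)
      i <- i + 2L
    } else if (ch %in% .organic_subset) {
      at <- add_atom(ch, FALSE, 0L, NA_integer_)
      bracket_flag[at] <- FALSE
      connect(at)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      at <- add_atom(toupper(ch), TRUE, 0L, NA_integer_)
      bracket_flag[at] <- FALSE
      connect(at)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", "$", ":", "/", "\\")) {
      pend_bond <- ch
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) perr("unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      ring_event(as.integer(ch))
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > len) perr("truncated %nn ring closure")
      ring_event(as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_
      i <- i + 1L
    } else {
      perr(sprintf("unexpected character '%s' at position %d", ch, i))
    }
  }
  if (length(rings) > 0L) perr("unclosed ring bond")
  if (length(stack) > 0L) perr("unbalanced '('")
  if (n == 0L) perr("no atoms")

  atoms <- data.frame(element = el, aromatic = arom, charge = chg,
                      h = exh, stringsAsFactors = FALSE)
  bonds <- if (length(b1)) {
    data.frame(a1 = b1, a2 = b2, order = bord, aromatic = barom)
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = numeric(),
               aromatic = logical())
  }
  atoms$bracket <- bracket_flag[seq_len(n)]
  atoms$h <- .implicit_h(atoms, bonds)
  ring_info <- .ring_membership(n, bonds)
  atoms$in_ring <- ring_info$in_ring
  atoms$in_ring3 <- ring_info$in_ring3
  structure(list(atoms = atoms, bonds = bonds, smiles = smiles),
            class = "mcl_mol")
}

# Implicit hydrogen counts per the Daylight organic-subset convention.
# Aromatic atoms get +1 to their bond-order sum for the delocalised system.
.implicit_h <- function(atoms, bonds) {
  n <- nrow(atoms)
  bsum <- numeric(n)
  if (nrow(bonds) > 0L) {
    ords <- ifelse(bonds$aromatic, 1, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + ords[k]
      bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + ords[k]
    }
  }
  h <- atoms$h
  for (a in seq_len(n)) {
    if (atoms$bracket[a]) {            # bracket atoms: explicit H only
      if (is.na(h[a])) h[a] <- 0L
      next
    }
    vals <- .default_valences[[atoms$element[a]]]
    if (is.null(vals)) { h[a] <- 0L; next }
    if (atoms$aromatic[a]) {
      # aromatic atoms: lowest valence only, +1 for the delocalised system
      h[a] <- as.integer(max(0, round(vals[1] - (bsum[a] + 1))))
    } else {
      s <- bsum[a]
      v <- vals[vals >= s]
      h[a] <- if (length(v)) as.integer(round(v[1] - s)) else 0L
    }
  }
  as.integer(h)
}

# Ring membership via bridge detection (an edge is a ring edge iff it is
# not a bridge); 3-rings found directly from the adjacency lists.
.ring_membership <- function(n, bonds) {
  in_ring <- logical(n); in_ring3 <- logical(n)
  m <- nrow(bonds)
  if (m == 0L) return(list(in_ring = in_ring, in_ring3 = in_ring3))
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], k)
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], k)
  }
  other <- function(k, a) if (bonds$a1[k] == a) bonds$a2[k] else bonds$a1[k]
  disc <- integer(n); low <- integer(n); timer <- 0L
  is_bridge <- logical(m)
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    # iterative DFS with explicit stack (deep molecules must not overflow)
    st <- list(list(a = root, pe = 0L, ptr = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(st) > 0L) {
      fr <- st[[length(st)]]
      a <- fr$a
      if (fr$ptr <= length(adj[[a]])) {
        k <- adj[[a]][fr$ptr]
        st[[length(st)]]$ptr <- fr$ptr + 1L
        if (k == fr$pe) next
        b <- other(k, a)
        if (disc[b] == 0L) {
          timer <- timer + 1L; disc[b] <- low[b] <- timer
          st[[length(st) + 1L]] <- list(a = b, pe = k, ptr = 1L)
        } else {
          low[a] <- min(low[a], disc[b])
        }
      } else {
        st[[length(st)]] <- NULL
        if (length(st) > 0L) {
          pa <- st[[length(st)]]$a
          low[pa] <- min(low[pa], low[a])
          if (low[a] > disc[pa]) is_bridge[fr$pe] <- TRUE
        }
      }
    }
  }
  for (k in seq_len(m)) {
    if (!is_bridge[k]) {
      in_ring[bonds$a1[k]] <- TRUE
      in_ring[bonds$a2[k]] <- TRUE
    }
  }
  # triangles: neighbour lists intersect
  nb <- lapply(seq_len(n), function(a) {
    vapply(adj[[a]], other, integer(1), a = a)
  })
  for (k in seq_len(m)) {
    a <- bonds$a1[k]; b <- bonds$a2[k]
    common <- intersect(nb[[a]], nb[[b]])
    if (length(common) > 0L) {
      in_ring3[c(a, b, common)] <- TRUE
    }
  }
  list(in_ring = in_ring, in_ring3 = in_ring3)
}

#' Element counts (molecular formula) of a parsed molecule
#'
#' @param mol An `mcl_mol` from [parse_smiles()].
#' @return Named integer vector of element counts including `H`.
#' @export
mol_formula <- function(mol) {
  stopifnot(inherits(mol, "mcl_mol"))
  counts <- table(mol$atoms$element)
  out <- as.integer(counts); names(out) <- names(counts)
  h <- sum(mol$atoms$h)
  if (h > 0L) out["H"] <- (if ("H" %in% names(out)) out[["H"]] else 0L) + h
  out[order(names(out))]
}

#' Monoisotopic mass of a parsed molecule
#'
#' @param mol An `mcl_mol` from [parse_smiles()].
#' @return Monoisotopic mass in Da.
#' @export
mol_monoisotopic_mass <- function(mol) formula_mass(mol_formula(mol))
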