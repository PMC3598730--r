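# Independent oracles used across the suite.

# brute-force admissible-context count: enumerate all assignments over the
# predecessors and filter, without reusing enumerateContexts' internals
oracleContextCount <- function(pim, node) {
  preds <- predecessorsOf(pim, node)
  n <- nrow(preds)
  asg <- if (n == 0L) matrix(integer(0), nrow = 1L) else
    as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  me <- mutuallyExclusiveInputs(pim, node)
  keep <- apply(asg, 1, function(bits) {
    if (any(bits[preds$kind == "all_or_none"] == 0L)) return(FALSE)
    if (nrow(me)) {
      for (r in seq_len(nrow(me))) {
        if (bits[match(me$a[r], preds$id)] == 1L &&
            bits[match(me$b[r], preds$id)] == 1L) return(FALSE)
      }
    }
    TRUE
  })
  k <- sum(keep)
  p <- processNodes(pim)
  if (p$type[match(node, p$id)] == "homodimerization") k * (k + 1) / 2 else k
}

# evaluate a gate's DNF (terms of "x"/"!x" literals) on a boolean assignment
oracleEvalTerms <- function(terms, assign) {
  if (is.null(terms)) return(TRUE)
  if (!length(terms)) return(FALSE)
  any(vapply(terms, function(t) {
    if (!length(t)) return(TRUE)
    all(vapply(t, function(l) {
      if (startsWith(l, "!")) !assign[[sub("^!", "", l)]] else assign[[l]]
    }, logical(1)))
  }, logical(1)))
}

# evaluate a {0,1,-} product-term vector (as from minimizeDnf) on minterm m
oracleEvalTermStrings <- function(terms, m, nVars) {
  if (!length(terms)) return(FALSE)
  for (t in terms) {
    bits <- if (nVars) strsplit(t, "")[[1]] else character(0)
    ok <- TRUE
    for (k in seq_len(nVars)) {
      if (bits[k] == "-") next
      have <- if (bitwAnd(m, 2^(nVars - k)) > 0) "1" else "0"
      if (have != bits[k]) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# minimal BNGL grammar check: block structure, rule syntax, paired bonds
checkBnglGrammar <- function(lines) {
  blocks <- c("parameters", "molecule types", "seed species", "reaction rules")
  for (b in blocks) {
    if (sum(lines == sprintf("begin %s", b)) != 1L ||
        sum(lines == sprintf("end %s", b)) != 1L)
      return(sprintf("block '%s' malformed", b))
  }
  a <- which(lines == "begin reaction rules")
  z <- which(lines == "end reaction rules")
  pat <- "^[A-Za-z][A-Za-z0-9_]*\\(([A-Za-z][A-Za-z0-9_]*(~[A-Za-z]+)?(!\\d+)?)?(,[A-Za-z][A-Za-z0-9_]*(~[A-Za-z]+)?(!\\d+)?)*\\)$"
  for (ln in lines[(a + 1):(z - 1)]) {
    if (grepl("^\\s*(#|$)", ln)) next
    ln2 <- sub("^\\s+", "", ln)
    m <- regmatches(ln2, regexec("^(.*?) (<->|->) (.*?) (\\S+)(, (\\S+))?$", ln2,
                                 perl = TRUE))[[1]]
    if (!length(m)) return(sprintf("rule line not parseable: %s", ln2))
    for (side in c(m[2], m[4])) {
      if (side == "0") next
      bonds <- integer(0)
      for (cx in strsplit(side, " \\+ ")[[1]]) {
        for (inst in strsplit(cx, ".", fixed = TRUE)[[1]]) {
          # re-join molecule(...) pieces split on "." is not needed: instance
          # separators never occur inside parentheses for this generator
          if (!grepl(pat, inst)) return(sprintf("bad pattern '%s'", inst))
        }
        bonds <- c(bonds, as.integer(unlist(regmatches(cx, gregexpr("(?<=!)\\d+", cx, perl = TRUE)))))
      }
      tb <- table(bonds)
      if (length(tb) && any(tb != 2L))
        return(sprintf("unpaired bond label on side '%s'", side))
    }
  }
  TRUE
}

# multiset of context-site tokens of one rule side, excluding the node's
# reaction-center sites
contextTokens <- function(side, centerSites) {
  if (side == "0") return(character(0))
  toks <- character(0)
  for (cx in strsplit(side, " \\+ ")[[1]]) {
    for (inst in strsplit(cx, ".", fixed = TRUE)[[1]]) {
      m <- regmatches(inst, regexec("^([A-Za-z][A-Za-z0-9_]*)\\((.*)\\)$", inst))[[1]]
      mol <- m[2]
      if (!nchar(m[3])) next
      for (s in strsplit(m[3], ",")[[1]]) {
        site <- sub("[~!].*$", "", s)
        if (paste(mol, site, sep = ".") %in% centerSites) next
        toks <- c(toks, paste0(mol, ":", s))
      }
    }
  }
  sort(toks)
}

centerSitesOf <- function(pim, node) {
  p <- processNodes(pim)
  p <- p[p$id == node, ]
  out <- character(0)
  if (!is.na(p$site1)) out <- paste(p$mol1, p$site1, sep = ".")
  if (!is.na(p$mol2)) out <- c(out, paste(p$mol2, p$site2, sep = "."))
  out
}

# the competing-binding special case: A and B both bind R at s1, which
# influences binding of C at s2
buildCompetingBindingExample <- function() {
  mols <- list(A = "b1", B = "b1", C = "b1", R = c("s1", "s2"))
  pr <- data.frame(
    id = 1:3, type = "binding",
    mol1 = c("A", "B", "C"), site1 = "b1",
    mol2 = "R", site2 = c("s1", "s1", "s2"),
    reversible = TRUE, stringsAsFactors = FALSE)
  inf <- data.frame(source = c(1L, 2L), target = 3L, kind = "plain",
                    stringsAsFactors = FALSE)
  skel <- Pim(mols, pr, inf, tables = list(),
              thresholds = list(t1 = 0.01, t2 = 0.1))
  rows3 <- data.frame(ctx = c("00", "01", "10"), kfw = c(0.005, 1, 1),
                      kbw = 1, y = NA_character_, stringsAsFactors = FALSE)
  rows3 <- rbind(rows3, data.frame(ctx = "11", kfw = NA_real_, kbw = NA_real_,
                                   y = "1", stringsAsFactors = FALSE))
  pimod:::fillTables(skel, list(
    `1` = data.frame(ctx = "", kfw = 1, kbw = 1, y = NA_character_),
    `2` = data.frame(ctx = "", kfw = 1, kbw = 1, y = NA_character_),
    `3` = rows3))
}

# one molecule binding two different pre-modified sites through a single
# binding site: forces the auxiliary L-node insertion
buildSharedPartnerExample <- function() {
  mols <- list(A = "b1", R = c("p1", "p2"))
  pr <- data.frame(
    id = 1:4,
    type = c("modification", "modification", "binding", "binding"),
    mol1 = c("R", "R", "A", "A"), site1 = c("p1", "p2", "b1", "b1"),
    mol2 = c(NA, NA, "R", "R"), site2 = c(NA, NA, "p1", "p2"),
    reversible = TRUE, stringsAsFactors = FALSE)
  inf <- data.frame(source = c(1L, 2L), target = c(3L, 4L),
                    kind = "all_or_none", stringsAsFactors = FALSE)
  skel <- Pim(mols, pr, inf, tables = list(),
              thresholds = list(t1 = 0.01, t2 = 0.1))
  one <- function(ctx) data.frame(ctx = ctx, kfw = 1, kbw = 1,
                                  y = NA_character_, stringsAsFactors = FALSE)
  pimod:::fillTables(skel, list(`1` = one(""), `2` = one(""),
                                `3` = one("1"), `4` = one("1")))
}

# modification feeding a homodimerization (duplicated-input table)
buildHomodimerExample <- function() {
  mols <- list(A = c("p1", "d"))
  pr <- data.frame(
    id = 1:2, type = c("modification", "homodimerization"),
    mol1 = "A", site1 = c("p1", "d"), mol2 = NA_character_,
    site2 = NA_character_, reversible = TRUE, stringsAsFactors = FALSE)
  inf <- data.frame(source = 1L, target = 2L, kind = "plain",
                    stringsAsFactors = FALSE)
  skel <- Pim(mols, pr, inf, tables = list(),
              thresholds = list(t1 = 0.01, t2 = 0.1))
  pimod:::fillTables(skel, list(
    `1` = data.frame(ctx = "", kfw = 1, kbw = 1, y = NA_character_),
    `2` = data.frame(ctx = c("00", "01", "11"), kfw = c(0.005, 0.05, 1),
                     kbw = 1, y = NA_character_, stringsAsFactors = FALSE)))
}

# binding gated by ubiquitination-dependent degradation (delay edge)
buildDegradationExample <- function() {
  mols <- list(A = c("b1", "ub"), R = "b1")
  pr <- data.frame(
    id = 1:3, type = c("binding", "modification", "degradation"),
    mol1 = c("A", "A", "A"), site1 = c("b1", "ub", NA),
    mol2 = c("R", NA, NA), site2 = c("b1", NA, NA),
    reversible = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  inf <- data.frame(source = 2L, target = 3L, kind = "plain",
                    stringsAsFactors = FALSE)
  skel <- Pim(mols, pr, inf, tables = list(),
              thresholds = list(t1 = 0.01, t2 = 0.1))
  pimod:::fillTables(skel, list(
    `1` = data.frame(ctx = "", kfw = 1, kbw = 1, y = NA_character_),
    `2` = data.frame(ctx = "", kfw = 1, kbw = 1, y = NA_character_),
    `3` = data.frame(ctx = c("0", "1"), kfw = c(0.005, 1), kbw = NA_real_,
                     y = NA_character_, stringsAsFactors = FALSE)))
}
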