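# Shared test infrastructure: cached fixture profiles (the full-registry
# profile run is reused by several test files) and the two independent
# oracles -- RDKit substructure enumeration and exact-rational hypergeometric
# summation -- both driven through the system `python`.

.test_cache <- new.env(parent = emptyenv())

test_fixture_bundle <- function() {
  if (is.null(.test_cache$bundle)) {
    fx <- generate_fixtures(seed = 1L, n_per_class = 3L)
    reg <- efg_registry()
    mols1 <- normalize_molecules(fixture_molecules(fx, variant = 1L))
    mols2 <- normalize_molecules(fixture_molecules(fx, variant = 2L))
    .test_cache$bundle <- list(
      fx = fx, reg = reg, mols1 = mols1, mols2 = mols2,
      prof1 = profile_collection(mols1, reg),
      prof2 = profile_collection(mols2, reg))
  }
  .test_cache$bundle
}

# RDKit (via python) as an independent subgraph-enumeration oracle:
# counts distinct matched atom sets for every molecule x pattern pair.
rdkit_count_matrix <- function(smiles, mol_ids, smarts, group_ids) {
  mfile <- tempfile("mols"); pfile <- tempfile("pats"); ofile <- tempfile("out")
  on.exit(unlink(c(mfile, pfile, ofile)), add = TRUE)
  writeLines(paste(smiles, mol_ids, sep = "\t"), mfile)
  writeLines(paste(group_ids, smarts, sep = "\t"), pfile)
  script <- c(
    "import sys",
    "from rdkit import Chem, RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "mols = [l.rstrip(chr(10)).split(chr(9)) for l in open(sys.argv[1])]",
    "pats = [l.rstrip(chr(10)).split(chr(9)) for l in open(sys.argv[2])]",
    "ms = [(mid, Chem.MolFromSmiles(smi)) for smi, mid in mols]",
    "out = open(sys.argv[3], 'w')",
    "for gid, sm in pats:",
    "    p = Chem.MolFromSmarts(sm)",
    "    row = [gid]",
    "    for mid, m in ms:",
    "        if m is None or p is None:",
    "            row.append('NA')",
    "        else:",
    "            row.append(str(len(m.GetSubstructMatches(p, uniquify=True, maxMatches=100000))))",
    "    out.write(chr(9).join(row) + chr(10))",
    "out.close()")
  pyf <- tempfile(fileext = ".py")
  on.exit(unlink(pyf), add = TRUE)
  writeLines(script, pyf)
  status <- system2("python", c(pyf, mfile, pfile, ofile))
  stopifnot(status == 0L)
  tab <- utils::read.delim(ofile, header = FALSE, stringsAsFactors = FALSE)
  m <- t(as.matrix(tab[, -1, drop = FALSE]))
  dimnames(m) <- list(mol_ids, tab[[1]])
  mode(m) <- "integer"
  m
}

# exact-rational hypergeometric upper tails via python fractions
exact_hypergeom_oracle <- function(k, K, n, N) {
  infile <- tempfile("hg"); ofile <- tempfile("hgout")
  on.exit(unlink(c(infile, ofile)), add = TRUE)
  utils::write.table(data.frame(k, K, n, N), infile,
                     row.names = FALSE, col.names = FALSE)
  script <- c(
    "import sys",
    "from fractions import Fraction",
    "from math import comb",
    "out = open(sys.argv[2], 'w')",
    "for line in open(sys.argv[1]):",
    "    k, K, n, N = map(int, line.split())",
    "    tot = comb(N, n)",
    "    s = sum(Fraction(comb(K, x) * comb(N - K, n - x), tot)",
    "            for x in range(k, min(n, K) + 1))",
    "    out.write(repr(float(s)) + chr(10))",
    "out.close()")
  pyf <- tempfile(fileext = ".py")
  on.exit(unlink(pyf), add = TRUE)
  writeLines(script, pyf)
  status <- system2("python", c(pyf, infile, ofile))
  stopifnot(status == 0L)
  as.numeric(readLines(ofile))
}

# heavy atoms of a SMILES, counted lexically (independent of any chemistry
# engine): bracket atoms plus bare organic-subset symbols
lexical_heavy_atoms <- function(smi) {
  no_br <- gsub("\\[[^]]*\\]", "Q", smi)   # each bracket atom -> one token
  toks <- gregexpr("Q|Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s", no_br)[[1]]
  if (toks[1] == -1L) 0L else length(toks)
}
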