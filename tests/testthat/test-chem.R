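# Reference descriptor values for the fixed panel were computed with an
# independent implementation of the published Wildman-Crippen and Ertl
# contribution tables (RDKit 2024.09) and frozen here.
chem_panel <- local({
  txt <- "
methane\tC\t16.043\t0\t0.6361
ethane\tCC\t30.07\t0\t1.0262
ethanol\tCCO\t46.069\t20.23\t-0.0014
acetic acid\tCC(=O)O\t60.052\t37.3\t0.0909
benzene\tc1ccccc1\t78.114\t0\t1.6866
toluene\tCc1ccccc1\t92.141\t0\t1.99502
phenol\tOc1ccccc1\t94.113\t20.23\t1.3922
pyridine\tc1ccncc1\t79.102\t12.89\t1.0816
aniline\tNc1ccccc1\t93.129\t26.02\t1.2688
nitrobenzene\tO=[N+]([O-])c1ccccc1\t123.111\t43.14\t1.5948
anisole\tCOc1ccccc1\t108.14\t9.23\t1.6952
benzamide\tNC(=O)c1ccccc1\t121.139\t43.09\t0.7855
acetone\tCC(C)=O\t58.08\t17.07\t0.5953
diethyl ether\tCCOCC\t74.123\t9.23\t1.0428
chloroform\tClC(Cl)Cl\t119.378\t0\t1.9864
urea\tNC(N)=O\t60.056\t69.11\t-0.9762
naphthalene\tc1ccc2ccccc2c1\t128.174\t0\t2.8398
thiophene\tc1ccsc1\t84.143\t0\t1.7481
acetonitrile\tCC#N\t41.053\t23.79\t0.52988
dmso\tCS(C)=O\t78.136\t17.07\t-0.0053
zileuton\tCC(c1cc2ccccc2s1)N(O)C(N)=O\t236.296\t66.56\t2.7322
TCDD\tClc1cc2Oc3cc(Cl)c(Cl)cc3Oc2cc1Cl\t321.974\t18.46\t6.1982
caffeic acid\tO=C(O)C=Cc1ccc(O)c(O)c1\t180.159\t77.76\t1.1956
caffeine\tCn1cnc2c1c(=O)n(C)c(=O)n2C\t194.194\t61.82\t-1.0293"
  read.delim(text = txt, header = FALSE,
             col.names = c("name", "smiles", "mw", "tpsa", "clogp"))
})

test_that("SMILES parsing perceives atoms, rings and hydrogens", {
  m <- parse_smiles("C")
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$implicit_h, 4L)

  benz <- parse_smiles("c1ccccc1")
  expect_equal(nrow(benz$atoms), 6L)
  expect_true(all(benz$atoms$aromatic))
  expect_true(all(benz$atoms$in_ring))
  expect_length(benz$rings, 1L)

  # Kekule benzene is perceived as aromatic
  kek <- parse_smiles("C1=CC=CC=C1")
  expect_true(all(kek$atoms$aromatic))
  expect_equal(molecular_weight(kek), molecular_weight(benz))

  expect_error(parse_smiles("C("), "syntax error")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles(""), "syntax error")
  expect_error(parse_smiles("C(C)(C)(C)(C)C"), "valence")
})

test_that("molecular weight matches hand sums and is fragment-additive", {
  expect_equal(molecular_weight("C"), 16.043, tolerance = 1e-3)
  expect_equal(molecular_weight("O"), 18.015, tolerance = 1e-3)
  # zileuton is C11H12N2O2S; the printed weight rounds to 236
  expect_equal(round(molecular_weight("CC(c1cc2ccccc2s1)N(O)C(N)=O")), 236)

  set.seed(5)
  frags <- c("CCO", "c1ccccc1", "NC(N)=O", "CC(=O)O", "CS(C)=O")
  for (i in 1:10) {
    a <- sample(frags, 1); b <- sample(frags, 1)
    expect_equal(molecular_weight(paste0(a, ".", b)),
                 molecular_weight(a) + molecular_weight(b),
                 tolerance = 1e-9)
  }
})

test_that("donor/acceptor counts follow the original N/O conventions", {
  expect_equal(count_hbd("O"), 1L)       # water
  expect_equal(count_hba("O"), 1L)
  expect_equal(count_hbd("CCO"), 1L)     # ethanol
  expect_equal(count_hba("CCO"), 1L)
  expect_equal(count_hbd("NC(N)=O"), 2L) # urea: two NH2 donate
  expect_equal(count_hba("NC(N)=O"), 3L) # 2 N + 1 O accept
  expect_equal(count_hbd("c1ccccc1"), 0L)
})

test_that("TPSA reproduces published single-fragment values", {
  expect_equal(tpsa("c1ccccc1"), 0)
  expect_equal(tpsa("CCOCC"), 9.23)      # one ether oxygen
  expect_equal(tpsa("c1ccncc1"), 12.89)  # one aromatic nitrogen
  expect_equal(tpsa("CCO"), 20.23)       # hydroxyl
  expect_equal(tpsa("CC(C)=O"), 17.07)   # carbonyl
  # S contributes only in extended mode
  expect_equal(tpsa("CCSCC"), 0)
  expect_equal(tpsa("CCSCC", extended = TRUE), 25.30)
})

test_that("rotatable bonds follow the counting rule", {
  expect_equal(rotatable_bonds("CC"), 0L)          # terminal atoms
  expect_equal(rotatable_bonds("CCCC"), 1L)        # n-butane central bond
  expect_equal(rotatable_bonds("c1ccccc1"), 0L)    # ring bonds
  expect_equal(rotatable_bonds("CCCCC"), 2L)
  expect_equal(rotatable_bonds("CC(=O)NC"), 0L)    # amide C-N excluded
  expect_equal(rotatable_bonds("CCOC"), 1L)   # terminal methyl ether
  expect_equal(rotatable_bonds("CCOCC"), 2L)
})

test_that("clogP and TPSA match the frozen reference panel", {
  for (i in seq_len(nrow(chem_panel))) {
    mol <- parse_smiles(chem_panel$smiles[i])
    expect_equal(crippen_clogp(mol), chem_panel$clogp[i], tolerance = 1e-6,
                 label = paste("clogp", chem_panel$name[i]))
    expect_equal(tpsa(mol), chem_panel$tpsa[i], tolerance = 1e-6,
                 label = paste("tpsa", chem_panel$name[i]))
    expect_equal(molecular_weight(mol), chem_panel$mw[i], tolerance = 0.05,
                 label = paste("mw", chem_panel$name[i]))
  }
})

test_that("methane clogP decomposes into the published two-row sum", {
  # one aliphatic C entry (0.1441) plus four hydrocarbon H entries (0.1230)
  expect_equal(crippen_clogp("C"), 0.1441 + 4 * 0.1230, tolerance = 1e-9)
})

test_that("clogP banding uses the printed thresholds", {
  expect_equal(clogp_band(-1.1), "aqueous")
  expect_equal(clogp_band(6.12), "high")
  expect_equal(clogp_band(0.0), "optimal")  # zero is not negative
  expect_equal(clogp_band(4.999), "optimal")
  expect_equal(clogp_band(5.0), "high")
  expect_error(clogp_band(NaN), "non-finite")
})

test_that("zileuton passes the clogP gates that TCDD fails", {
  zil <- crippen_clogp("CC(c1cc2ccccc2s1)N(O)C(N)=O")
  tcdd <- crippen_clogp("Clc1cc2Oc3cc(Cl)c(Cl)cc3Oc2cc1Cl")
  expect_lte(zil, 5.0)
  expect_gt(tcdd, zil)
  expect_equal(clogp_band(zil), "optimal")
  expect_equal(clogp_band(tcdd), "high")
})

test_that("fingerprints are deterministic, discriminative and never empty", {
  f1 <- fingerprint("C")
  expect_identical(f1, fingerprint("C"))
  expect_false(identical(f1, fingerprint("c1ccccc1")))
  panel <- synthetic_compound_panel()
  for (smi in panel$smiles) {
    expect_gt(sum(fingerprint(smi)), 0)
  }
  expect_length(fingerprint("CCO", n_bits = 128L), 128L)
})

test_that("Lipinski violation counting matches a brute-force rule check", {
  rule <- lipinski_config()
  set.seed(99)
  for (case in 1:1000) {
    d <- data.frame(mw = runif(1, 50, 900), hbd = sample(0:12, 1),
                    hba = sample(0:15, 1), tpsa = runif(1, 0, 250),
                    rotb = sample(0:16, 1))
    brute <- sum(d$mw >= 500, d$hbd > 5, d$hba > 10, d$tpsa > 140,
                 d$rotb > 10)
    expect_identical(lipinski_violations(d, rule), as.integer(brute))
  }
})
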