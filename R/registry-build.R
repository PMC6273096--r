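#' @title Programmatic construction of the shipped registry
#' @description
#' The shipped registry is assembled from four blocks: the 200-entry base set
#' of classical functional-group families (re-encoded as SMARTS), 15
#' reactivity-motivated extensions, the 353-entry systematic HS/LS
#' heterocycle taxonomy, and 15 periodic-table element categories -- 583
#' patterns in total. `build_default_registry()` regenerates the whole table;
#' the result is serialized to `inst/extdata/efg_registry.tsv` so users can
#' fine-tune individual patterns without touching code.
#' @name efg-registry-build
NULL

# Shorthands used across the base set. The nitro group is written as an
# alternation so that both the hypervalent (N(=O)=O) and the
# charge-separated ([N+](=O)[O-]) input conventions match after
# normalization.
.NITRO <- "[$([NX3](=[OX1])=[OX1]),$([NX3+](=[OX1])[OX1-])]"
.AZIDE <- "[$([NX2]=[NX2+]=[NX1-]),$([NX2]=[NX2]=[NX1])]"

# the 200-entry classical base set: list(group_id, name, smarts)
.checkmol_base_defs <- function() list(
  list("cation", "Cation", "[+;!$([+]~[-])]"),
  list("anion", "Anion", "[-;!$([-]~[+])]"),
  list("carbonyl", "Carbonyl group", "[CX3]=[OX1]"),
  list("aldehyde", "Aldehyde", "[$([CX3H1](=[OX1])[#6]),$([CX3H2]=[OX1])]"),
  list("ketone", "Ketone", "[#6][CX3](=[OX1])[#6]"),
  list("thiocarbonyl", "Thiocarbonyl group", "[CX3]=[SX1]"),
  list("thioaldehyde", "Thioaldehyde", "[$([CX3H1](=[SX1])[#6]),$([CX3H2]=[SX1])]"),
  list("thioketone", "Thioketone", "[#6][CX3](=[SX1])[#6]"),
  list("imine", "Imine", "[CX3]=[NX2;!$([NX2][OX2]);!$([NX2][NX3])]"),
  list("hydrazone", "Hydrazone", "[CX3]=[NX2][NX3]"),
  list("semicarbazone", "Semicarbazone", "[CX3]=[NX2][NX3][CX3](=[OX1])[NX3]"),
  list("thiosemicarbazone", "Thiosemicarbazone", "[CX3]=[NX2][NX3][CX3](=[SX1])[NX3]"),
  list("oxime", "Oxime", "[CX3]=[NX2][OX2H1]"),
  list("oxime_ether", "Oxime ether", "[CX3]=[NX2][OX2][#6]"),
  list("ketene", "Ketene", "[CX3]=[CX2]=[OX1]"),
  list("ketene_acetal_deriv", "Ketene acetal or derivative", "[CX3]=[CX3]([OX2,SX2,NX3])[OX2,SX2,NX3]"),
  list("carbonyl_hydrate", "Carbonyl hydrate (gem-diol)", "[CX4]([OX2H])[OX2H]"),
  list("hemiacetal", "Hemiacetal", "[OX2H][CX4][OX2][#6]"),
  list("acetal", "Acetal", "[#6][OX2][CX4][OX2][#6]"),
  list("hemiaminal", "Hemiaminal", "[OX2H][CX4][NX3]"),
  list("aminal", "Aminal", "[NX3][CX4][NX3]"),
  list("thiohemiaminal", "Thiohemiaminal", "[SX2H][CX4][NX3]"),
  list("thioacetal", "Thioacetal", "[#6][SX2][CX4][SX2][#6]"),
  list("enamine", "Enamine", "[NX3][CX3]=[CX3]"),
  list("enol", "Enol", "[OX2H][CX3]=[CX3]"),
  list("enol_ether", "Enol ether", "[#6][OX2][CX3]=[CX3]"),
  list("hydroxy", "Hydroxy group", "[OX2H][#6]"),
  list("alcohol", "Alcohol", "[OX2H][CX4]"),
  list("prim_alcohol", "Primary alcohol", "[OX2H][CX4H2]"),
  list("sec_alcohol", "Secondary alcohol", "[OX2H][CX4H1]([#6])[#6]"),
  list("tert_alcohol", "Tertiary alcohol", "[OX2H][CX4]([#6])([#6])[#6]"),
  list("diol_12", "1,2-diol", "[OX2H][CX4][CX4][OX2H]"),
  list("aminoalcohol_12", "1,2-aminoalcohol", "[OX2H][CX4][CX4][NX3;!$([NX3][CX3]=[OX1,SX1,NX2])]"),
  list("phenol", "Phenol", "[OX2H][c]"),
  list("diphenol_12", "1,2-diphenol", "[OX2H]c1c([OX2H])cccc1"),
  list("enediol", "Enediol", "[OX2H][CX3]=[CX3][OX2H]"),
  list("ether", "Ether", "[OX2]([#6;!$([CX3]=[OX1,SX1,NX2])])[#6;!$([CX3]=[OX1,SX1,NX2])]"),
  list("dialkyl_ether", "Dialkyl ether", "[OX2]([CX4])[CX4]"),
  list("alkyl_aryl_ether", "Alkyl aryl ether", "[OX2]([CX4])[c]"),
  list("diaryl_ether", "Diaryl ether", "[OX2]([c])[c]"),
  list("thioether", "Thioether", "[SX2]([#6;!$([CX3]=[OX1,SX1,NX2])])[#6;!$([CX3]=[OX1,SX1,NX2])]"),
  list("disulfide", "Disulfide", "[#6][SX2][SX2][#6]"),
  list("peroxide", "Peroxide", "[#6][OX2][OX2][#6]"),
  list("hydroperoxide", "Hydroperoxide", "[#6][OX2][OX2H]"),
  list("hydrazine_deriv", "Hydrazine derivative", "[NX3;!$([NX3][CX3]=[OX1,SX1,NX2])][NX3;!$([NX3][CX3]=[OX1,SX1,NX2])]"),
  list("hydroxylamine", "Hydroxylamine", "[NX3][OX2H]"),
  list("amine", "Amine", "[NX3+0;!$([NX3][CX3]=[OX1,SX1,NX2]);!$([NX3][#7,#8,#15,#16])]"),
  list("prim_amine", "Primary amine", "[NX3H2+0;!$([NX3][CX3]=[OX1,SX1,NX2]);!$([NX3][#7,#8])]"),
  list("prim_aliph_amine", "Primary aliphatic amine", "[NX3H2+0;!$([NX3][#7,#8])][CX4]"),
  list("prim_arom_amine", "Primary aromatic amine", "[NX3H2+0][c]"),
  list("sec_amine", "Secondary amine", "[NX3H1+0;!$([NX3][CX3]=[OX1,SX1,NX2]);!$([NX3][#7,#8])]([#6])[#6]"),
  list("sec_aliph_amine", "Secondary aliphatic amine", "[NX3H1+0;!$([NX3][#7,#8])]([CX4])[CX4]"),
  list("sec_mixed_amine", "Secondary mixed amine", "[NX3H1+0]([CX4])[c]"),
  list("sec_arom_amine", "Secondary aromatic amine", "[NX3H1+0]([c])[c]"),
  list("tert_amine", "Tertiary amine", "[NX3H0+0;!$([NX3][CX3]=[OX1,SX1,NX2]);!$([NX3][#7,#8]);!$([NX3]=*)]([#6])([#6])[#6]"),
  list("tert_aliph_amine", "Tertiary aliphatic amine", "[NX3H0+0;!$([NX3][#7,#8])]([CX4])([CX4])[CX4]"),
  list("tert_mixed_amine", "Tertiary mixed amine", "[NX3H0+0]([CX4])([c])[#6]"),
  list("tert_arom_amine", "Tertiary aromatic amine", "[NX3H0+0]([c])([c])[c]"),
  list("quat_ammonium", "Quaternary ammonium salt", "[NX4+]"),
  list("n_oxide", "N-oxide", "[$([NX4+][OX1-]),$([nX3+][OX1-])]"),
  list("halogen_deriv", "Halogen derivative", "[F,Cl,Br,I][#6]"),
  list("alkyl_halide", "Alkyl halide", "[F,Cl,Br,I][CX4]"),
  list("alkyl_fluoride", "Alkyl fluoride", "[F][CX4]"),
  list("alkyl_chloride", "Alkyl chloride", "[Cl][CX4]"),
  list("alkyl_bromide", "Alkyl bromide", "[Br][CX4]"),
  list("alkyl_iodide", "Alkyl iodide", "[I][CX4]"),
  list("aryl_halide", "Aryl halide", "[F,Cl,Br,I][c]"),
  list("aryl_fluoride", "Aryl fluoride", "[F][c]"),
  list("aryl_chloride", "Aryl chloride", "[Cl][c]"),
  list("aryl_bromide", "Aryl bromide", "[Br][c]"),
  list("aryl_iodide", "Aryl iodide", "[I][c]"),
  list("organometallic", "Organometallic compound", "[#6]~[Li,Na,K,Rb,Cs,Be,Mg,Ca,Sr,Ba,Al,Ga,In,Tl,Sn,Pb,Bi,Zn,Cd,Hg,Cu,Fe,Ti,Zr,Mn,Ni,Co,Pd,Pt]"),
  list("organolithium", "Organolithium compound", "[#6][Li]"),
  list("organomagnesium", "Organomagnesium compound", "[#6][Mg]"),
  list("carboxylic_deriv", "Carboxylic acid derivative", "[CX3](=[OX1])[#7,#8,#9,#16,#17,#35,#53;!$([OX1])]"),
  list("carboxylic_acid", "Carboxylic acid", "[CX3](=[OX1])[OX2H]"),
  list("carboxylate", "Carboxylic acid salt", "[CX3](=[OX1])[OX1-]"),
  list("carboxylic_ester", "Carboxylic acid ester", "[CX3](=[OX1])[OX2][#6]"),
  list("lactone", "Lactone", "[CX3;R](=[OX1])[OX2;R][#6;R]"),
  list("carboxamide", "Carboxylic acid amide", "[CX3](=[OX1])[NX3]"),
  list("prim_amide", "Primary carboxylic acid amide", "[CX3](=[OX1])[NX3H2]"),
  list("sec_amide", "Secondary carboxylic acid amide", "[CX3](=[OX1])[NX3H1][#6]"),
  list("tert_amide", "Tertiary carboxylic acid amide", "[CX3](=[OX1])[NX3]([#6])[#6]"),
  list("lactam", "Lactam", "[CX3;R](=[OX1])[NX3;R]"),
  list("acid_hydrazide", "Carboxylic acid hydrazide", "[CX3](=[OX1])[NX3][NX3]"),
  list("acid_azide", "Carboxylic acid azide", paste0("[CX3](=[OX1])", .AZIDE)),
  list("hydroxamic_acid", "Hydroxamic acid", "[CX3](=[OX1])[NX3][OX2H]"),
  list("amidine", "Carboxylic acid amidine", "[NX3][CX3]=[NX2;!$([NX2][NX3])]"),
  list("amidrazone", "Carboxylic acid amidrazone", "[NX3][CX3]=[NX2][NX3]"),
  list("nitrile", "Carbonitrile", "[CX2]#[NX1]"),
  list("acyl_halide", "Acyl halide", "[CX3](=[OX1])[F,Cl,Br,I]"),
  list("acyl_fluoride", "Acyl fluoride", "[CX3](=[OX1])[F]"),
  list("acyl_chloride", "Acyl chloride", "[CX3](=[OX1])[Cl]"),
  list("acyl_bromide", "Acyl bromide", "[CX3](=[OX1])[Br]"),
  list("acyl_iodide", "Acyl iodide", "[CX3](=[OX1])[I]"),
  list("acyl_cyanide", "Acyl cyanide", "[CX3](=[OX1])[CX2]#[NX1]"),
  list("imido_ester", "Imido ester", "[NX2]=[CX3][OX2][#6]"),
  list("imidoyl_halide", "Imidoyl halide", "[NX2]=[CX3][F,Cl,Br,I]"),
  list("thiocarboxylic_deriv", "Thiocarboxylic acid derivative", "[$([CX3](=[SX1])[#7,#8,#16]),$([CX3](=[OX1])[SX2])]"),
  list("thiocarboxylic_acid", "Thiocarboxylic acid", "[$([CX3](=[OX1])[SX2H]),$([CX3](=[SX1])[OX2H])]"),
  list("thiocarboxylic_ester", "Thiocarboxylic acid ester", "[$([CX3](=[OX1])[SX2][#6]),$([CX3](=[SX1])[OX2][#6])]"),
  list("thiolactone", "Thiolactone", "[CX3;R](=[OX1])[SX2;R][#6;R]"),
  list("thiocarboxamide", "Thiocarboxylic acid amide", "[CX3](=[SX1])[NX3]"),
  list("thiolactam", "Thiolactam", "[CX3;R](=[SX1])[NX3;R]"),
  list("imido_thioester", "Imidothioester", "[NX2]=[CX3][SX2][#6]"),
  list("oxohetarene", "Oxohetarene", "[OX1]=[#6;R]@[#7;R]@[#6;R]"),
  list("thioxohetarene", "Thioxohetarene", "[SX1]=[#6;R]@[#7;R]@[#6;R]"),
  list("iminohetarene", "Iminohetarene", "[NX2H1]=[#6;R]@[#7;R]@[#6;R]"),
  list("orthoester", "Carboxylic acid orthoester", "[CX4]([OX2][#6])([OX2][#6])[OX2][#6]"),
  list("amide_acetal", "Carboxylic acid amide acetal", "[CX4]([OX2][#6])([OX2][#6])[NX3]"),
  list("anhydride", "Carboxylic acid anhydride", "[CX3](=[OX1])[OX2][CX3]=[OX1]"),
  list("imide", "Carboxylic acid imide", "[CX3](=[OX1])[NX3][CX3]=[OX1]"),
  list("imide_unsubst", "Carboxylic acid imide, N-unsubstituted", "[CX3](=[OX1])[NX3H1][CX3]=[OX1]"),
  list("imide_subst", "Carboxylic acid imide, N-substituted", "[CX3](=[OX1])[NX3H0]([#6])[CX3]=[OX1]"),
  list("carbonic_deriv", "Carbonic acid derivative", "[CX3](=[OX1])([OX2,OX1-])[OX2,OX1-]"),
  list("carbonic_monoester", "Carbonic acid monoester", "[CX3](=[OX1])([OX2H])[OX2][#6]"),
  list("carbonic_diester", "Carbonic acid diester", "[#6][OX2][CX3](=[OX1])[OX2][#6]"),
  list("carbonic_ester_halide", "Carbonic acid ester halide (haloformate)", "[#6][OX2][CX3](=[OX1])[F,Cl,Br,I]"),
  list("thiocarbonic_deriv", "Thiocarbonic acid derivative", "[CX3](=[SX1])([OX2,SX2])[OX2,SX2]"),
  list("thiocarbonic_monoester", "Thiocarbonic acid monoester", "[CX3](=[SX1])([OX2H,SX2H])[OX2,SX2][#6]"),
  list("thiocarbonic_diester", "Thiocarbonic acid diester", "[#6][OX2,SX2][CX3](=[SX1])[OX2,SX2][#6]"),
  list("thiocarbonic_ester_halide", "Thiocarbonic acid ester halide", "[#6][OX2,SX2][CX3](=[SX1])[F,Cl,Br,I]"),
  list("carbamic_deriv", "Carbamic acid derivative", "[NX3][CX3](=[OX1])[OX2,OX1-,F,Cl,Br,I]"),
  list("carbamic_acid", "Carbamic acid", "[NX3][CX3](=[OX1])[OX2H]"),
  list("carbamate", "Carbamic acid ester (urethane)", "[NX3][CX3](=[OX1])[OX2][#6]"),
  list("carbamoyl_halide", "Carbamic acid halide", "[NX3][CX3](=[OX1])[F,Cl,Br,I]"),
  list("thiocarbamic_deriv", "Thiocarbamic acid derivative", "[NX3][CX3](=[SX1])[OX2,SX2,F,Cl,Br,I]"),
  list("thiocarbamic_acid", "Thiocarbamic acid", "[NX3][CX3](=[SX1])[OX2H,SX2H]"),
  list("thiocarbamic_ester", "Thiocarbamic acid ester", "[NX3][CX3](=[SX1])[OX2,SX2][#6]"),
  list("thiocarbamic_halide", "Thiocarbamic acid halide", "[NX3][CX3](=[SX1])[F,Cl,Br,I]"),
  list("urea", "Urea", "[NX3][CX3](=[OX1])[NX3]"),
  list("isourea", "Isourea", "[NX2]=[CX3]([NX3])[OX2]"),
  list("thiourea", "Thiourea", "[NX3][CX3](=[SX1])[NX3]"),
  list("isothiourea", "Isothiourea", "[NX2]=[CX3]([NX3])[SX2]"),
  list("guanidine", "Guanidine", "[NX3][CX3](=[NX2])[NX3]"),
  list("semicarbazide", "Semicarbazide", "[NX3][NX3][CX3](=[OX1])[NX3]"),
  list("thiosemicarbazide", "Thiosemicarbazide", "[NX3][NX3][CX3](=[SX1])[NX3]"),
  list("azide", "Azide", .AZIDE),
  list("azo", "Azo compound", "[#6][NX2]=[NX2][#6]"),
  list("diazonium", "Diazonium salt", "[#6][NX2+]#[NX1]"),
  list("isonitrile", "Isonitrile", "[#6][NX2+]#[CX1-]"),
  list("cyanate", "Cyanate", "[#6][OX2][CX2]#[NX1]"),
  list("isocyanate", "Isocyanate", "[#6][NX2]=[CX2]=[OX1]"),
  list("thiocyanate", "Thiocyanate", "[#6][SX2][CX2]#[NX1]"),
  list("isothiocyanate", "Isothiocyanate", "[#6][NX2]=[CX2]=[SX1]"),
  list("carbodiimide", "Carbodiimide", "[NX2]=[CX2]=[NX2]"),
  list("nitroso", "Nitroso compound", "[#6][NX2]=[OX1]"),
  list("nitro", "Nitro group", .NITRO),
  list("nitrite_ester", "Nitrite ester", "[#6][OX2][NX2]=[OX1]"),
  list("nitrate_ester", "Nitrate ester", paste0("[#6][OX2]", sub("\\]$", ";$([NX3]~[OX2])]", .NITRO))),
  list("sulfuric_deriv", "Sulfuric acid derivative", "[SX4](=[OX1])(=[OX1])([OX2,OX1-])[OX2,OX1-]"),
  list("sulfuric_acid", "Sulfuric acid", "[SX4](=[OX1])(=[OX1])([OX2H])[OX2H]"),
  list("sulfuric_monoester", "Sulfuric acid monoester", "[SX4](=[OX1])(=[OX1])([OX2H])[OX2][#6]"),
  list("sulfuric_diester", "Sulfuric acid diester", "[#6][OX2][SX4](=[OX1])(=[OX1])[OX2][#6]"),
  list("sulfuric_amide_ester", "Sulfuric acid amide ester", "[NX3][SX4](=[OX1])(=[OX1])[OX2][#6]"),
  list("sulfuric_amide", "Sulfuric acid amide", "[NX3][SX4](=[OX1])(=[OX1])[OX2H,OX1-]"),
  list("sulfuric_diamide", "Sulfuric acid diamide", "[NX3][SX4](=[OX1])(=[OX1])[NX3]"),
  list("sulfuryl_halide", "Sulfuryl halide", "[F,Cl,Br,I][SX4](=[OX1])(=[OX1])[OX2,F,Cl,Br,I]"),
  list("sulfonic_deriv", "Sulfonic acid derivative", "[#6][SX4](=[OX1])(=[OX1])[!#6]"),
  list("sulfonic_acid", "Sulfonic acid", "[#6][SX4](=[OX1])(=[OX1])[OX2H,OX1-]"),
  list("sulfonic_ester", "Sulfonic acid ester", "[#6][SX4](=[OX1])(=[OX1])[OX2][#6]"),
  list("sulfonamide", "Sulfonamide", "[#6][SX4](=[OX1])(=[OX1])[NX3]"),
  list("sulfonyl_halide", "Sulfonyl halide", "[#6][SX4](=[OX1])(=[OX1])[F,Cl,Br,I]"),
  list("sulfone", "Sulfone", "[#6][SX4](=[OX1])(=[OX1])[#6]"),
  list("sulfoxide", "Sulfoxide", "[#6][SX3](=[OX1])[#6]"),
  list("sulfinic_deriv", "Sulfinic acid derivative", "[#6][SX3](=[OX1])[!#6]"),
  list("sulfinic_acid", "Sulfinic acid", "[#6][SX3](=[OX1])[OX2H,OX1-]"),
  list("sulfinic_ester", "Sulfinic acid ester", "[#6][SX3](=[OX1])[OX2][#6]"),
  list("sulfinic_halide", "Sulfinic acid halide", "[#6][SX3](=[OX1])[F,Cl,Br,I]"),
  list("sulfinic_amide", "Sulfinic acid amide", "[#6][SX3](=[OX1])[NX3]"),
  list("sulfenic_deriv", "Sulfenic acid derivative", "[#6][SX2][OX2,NX3,F,Cl,Br,I]"),
  list("sulfenic_acid", "Sulfenic acid", "[#6][SX2][OX2H]"),
  list("sulfenic_ester", "Sulfenic acid ester", "[#6][SX2][OX2][#6]"),
  list("sulfenic_halide", "Sulfenic acid halide", "[#6][SX2][F,Cl,Br,I]"),
  list("sulfenic_amide", "Sulfenic acid amide", "[#6][SX2][NX3]"),
  list("thiol", "Thiol (mercaptan)", "[#6][SX2H]"),
  list("alkylthiol", "Alkylthiol", "[CX4][SX2H]"),
  list("arylthiol", "Arylthiol (thiophenol)", "[c][SX2H]"),
  list("phosphoric_deriv", "Phosphoric acid derivative", "[PX4](=[OX1])([OX2,OX1-,NX3,F,Cl,Br,I])([OX2,OX1-,NX3,F,Cl,Br,I])[OX2,OX1-,NX3,F,Cl,Br,I]"),
  list("phosphoric_acid", "Phosphoric acid", "[PX4](=[OX1])([OX2H,OX1-])([OX2,OX1-])[OX2,OX1-]"),
  list("phosphoric_ester", "Phosphoric acid ester", "[PX4](=[OX1])([OX2][#6])([OX2,OX1-])[OX2,OX1-]"),
  list("phosphoric_halide", "Phosphoric acid halide", "[PX4](=[OX1])([F,Cl,Br,I])([OX2,OX1-])[OX2,OX1-]"),
  list("phosphoric_amide", "Phosphoric acid amide", "[PX4](=[OX1])([NX3])([OX2,OX1-,NX3])[OX2,OX1-,NX3]"),
  list("thiophosphoric_deriv", "Thiophosphoric acid derivative", "[PX4](=[SX1])([OX2,SX2,OX1-,SX1-,NX3])([OX2,SX2,OX1-,SX1-,NX3])[OX2,SX2,OX1-,SX1-,NX3]"),
  list("phosphonic_deriv", "Phosphonic acid derivative", "[#6][PX4](=[OX1])([OX2,OX1-,NX3,F,Cl,Br,I])[OX2,OX1-,NX3,F,Cl,Br,I]"),
  list("phosphonic_acid", "Phosphonic acid", "[#6][PX4](=[OX1])([OX2H,OX1-])[OX2,OX1-]"),
  list("phosphonic_ester", "Phosphonic acid ester", "[#6][PX4](=[OX1])([OX2][#6])[OX2,OX1-]"),
  list("phosphine", "Phosphine", "[PX3;!$([PX3][!#6;!#1])]"),
  list("phosphine_oxide", "Phosphine oxide", "[PX4](=[OX1])([#6])([#6])[#6]"),
  list("boronic_deriv", "Boronic acid derivative", "[#6][BX3]([!#6])[!#6]"),
  list("boronic_acid", "Boronic acid", "[#6][BX3]([OX2H])[OX2H]"),
  list("boronic_ester", "Boronic acid ester", "[#6][BX3]([OX2][#6])[OX2]"),
  list("borinic_acid", "Borinic acid", "[#6][BX3]([#6])[OX2H]"),
  list("borinic_ester", "Borinic acid ester", "[#6][BX3]([#6])[OX2][#6]"),
  list("alkene", "Alkene", "[CX3]=[CX3]"),
  list("alkyne", "Alkyne", "[CX2]#[CX2]"),
  list("aromatic_compound", "Aromatic compound", "[a]"),
  list("heterocyclic_compound", "Heterocyclic compound", "[!#6;!#1;R]"),
  list("alpha_aminoacid", "Alpha-aminoacid", "[NX3H2,NX3H1;+0][CX4][CX3](=[OX1])[OX2H,OX1-]"),
  list("alpha_hydroxyacid", "Alpha-hydroxyacid", "[OX2H][CX4][CX3](=[OX1])[OX2H,OX1-]"))

checkmol_base_registry <- function() {
  rows <- lapply(.checkmol_base_defs(), function(d)
    functional_group(d[[1]], d[[2]], d[[3]], category = "checkmol_base"))
  as_registry(do.call(rbind, rows))
}

# reactivity-motivated extensions: the vinyl/alkynyl/allyl halide, alcohol
# and thiol series, amino(thio)phenols, quinones, and the aromatic/aliphatic
# split of the general nitro group.
reactivity_extension_registry <- function() {
  defs <- list(
    list("vinyl_halide", "Vinyl halide", "[F,Cl,Br,I][CX3]=[CX3]"),
    list("alkynyl_halide", "Alkynyl halide", "[F,Cl,Br,I][CX2]#[CX2]"),
    list("allyl_halide", "Allyl halide", "[F,Cl,Br,I][CX4][CX3]=[CX3]"),
    list("vinyl_alcohol", "Vinyl alcohol (enolic hydroxy)", "[OX2H][CX3]=[CX3][#6,#1]"),
    list("alkynyl_alcohol", "Alkynyl alcohol", "[OX2H][CX2]#[CX2]"),
    list("allyl_alcohol", "Allyl alcohol", "[OX2H][CX4][CX3]=[CX3]"),
    list("vinyl_thiol", "Vinyl thiol", "[SX2H][CX3]=[CX3]"),
    list("alkynyl_thiol", "Alkynyl thiol", "[SX2H][CX2]#[CX2]"),
    list("allyl_thiol", "Allyl thiol", "[SX2H][CX4][CX3]=[CX3]"),
    list("aminophenol", "2-aminophenol", "[OX2H]c1ccccc1[NX3H2]"),
    list("aminothiophenol", "2-aminothiophenol", "[SX2H]c1ccccc1[NX3H2]"),
    list("quinone_14", "para-quinone", "[OX1]=[CX3]1[CX3]=[CX3][CX3](=[OX1])[CX3]=[CX3]1"),
    list("quinone_12", "ortho-quinone", "[OX1]=[CX3]1[CX3](=[OX1])[CX3]=[CX3][CX3]=[CX3]1"),
    list("nitro_aromatic", "Aromatic nitro group", paste0(.NITRO, "[a]")),
    # attachment atom: any non-aromatic heavy atom except the nitro oxygens
    list("nitro_aliphatic", "Aliphatic nitro group", paste0(.NITRO, "[A;!$([OX1])]")))
  rows <- lapply(defs, function(d)
    functional_group(d[[1]], d[[2]], d[[3]], category = "reactivity_extension"))
  as_registry(do.call(rbind, rows))
}

#' Rebuild the full default registry
#'
#' Assembles the 583-entry shipped registry from its four programmatic
#' blocks: 200 classical base groups, 15 reactivity extensions, 353
#' systematic heterocycle classes and 15 periodic-table categories.
#'
#' @return an `efg_registry` with 583 rows, identical to the shipped
#'   `inst/extdata/efg_registry.tsv`.
#' @export
build_default_registry <- function() {
  reg <- as_registry(rbind(checkmol_base_registry(),
                           reactivity_extension_registry(),
                           heterocycle_registry(),
                           periodic_group_registry()))
  assert_registry(reg, origin = "default registry build")
  reg
}
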