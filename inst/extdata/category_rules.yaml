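# Default classification rule lists for the four functional categories.
#
# These are curated stand-ins assembled from widely used Pfam signal
# transduction / DNA-binding families and COG transporter / defense ids;
# substitute your own lists (same schema) for study-specific inventories.
#
# Schema (per category): pfam (domain accessions), cog_id (COG ids),
# cog_cat (single-letter COG functional categories).  The tcs entry is
# special: its role_logic splits pfam accessions into receiver domains and
# kinase-core domains; receiver-only -> RR, kinase-only -> HK, both ->
# hybrid.
version: 1
categories:
  tcs:
    role_logic:
      receiver:
        - PF00072   # Response_reg receiver domain
      kinase_core:
        - PF00512   # HisKA dimerisation/phosphoacceptor
        - PF07568   # HisKA_2
        - PF07730   # HisKA_3
        - PF07536   # HWE_HK
        - PF02518   # HATPase_c kinase ATPase core
        - PF13581   # HATPase_c_2
    pfam: []
    cog_id: []
    cog_cat: []
  tf:
    pfam:
      - PF00196   # GerE (LuxR-type HTH)
      - PF00165   # HTH_AraC
      - PF00356   # LacI
      - PF00392   # GntR
      - PF01047   # MarR
      - PF00440   # TetR_N
      - PF01381   # HTH_3 (Cro/CI)
      - PF04545   # Sigma70_r4
      - PF00455   # DeoR
      - PF01978   # TrmB
      - PF02082   # Rrf2
      - PF01638   # HxlR
    cog_id: []
    cog_cat: []
  transport:
    pfam: []
    cog_id:
      - COG1131   # ABC-type multidrug transport, ATPase
      - COG1132   # ABC-type multidrug transport, ATPase+permease
      - COG0444   # ABC-type dipeptide/oligopeptide transport, ATPase
      - COG0577   # ABC-type antimicrobial peptide transport, permease
      - COG0601   # ABC-type dipeptide transport, permease
      - COG1173   # ABC-type dipeptide/oligopeptide transport, permease
      - COG0834   # ABC-type amino acid transport, periplasmic
      - COG0747   # ABC-type dipeptide transport, periplasmic
      - COG4166   # ABC-type oligopeptide transport, periplasmic
      - COG1682   # ABC-type polysaccharide/polyol phosphate export
      - COG0842   # ABC-type multidrug transport, permease
      - COG1124   # ABC-type dipeptide/oligopeptide transport, ATPase
      - COG0765   # ABC-type amino acid transport, permease
      - COG1126   # ABC-type polar amino acid transport, ATPase
      - COG0683   # ABC-type branched-chain amino acid transport, periplasmic
      - COG0477   # MFS permease
      - COG2814   # MFS arabinose efflux permease
      - COG0697   # EamA-family permease
      - COG0531   # amino acid transporter
      - COG1593   # TRAP-type C4-dicarboxylate transporter
    cog_cat: []
  defense:
    pfam: []
    cog_id:
      - COG1680   # beta-lactamase class C
      - COG2367   # beta-lactamase class A
      - COG0286   # type I restriction-modification, M subunit
      - COG0610   # type I restriction-modification, R subunit
      - COG0732   # type I restriction-modification, S subunit
      - COG1715   # restriction endonuclease
      - COG3440   # restriction system protein
      - COG1357   # antiviral defense-associated repeat protein
    cog_cat:
      - V         # defense mechanisms
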