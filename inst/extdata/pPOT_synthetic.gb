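LOCUS       pPOT_synthetic        526 bp    DNA     circular SYN 01-APR-2024
DEFINITION  Synthetic stand-in tagging plasmid (not a published sequence).
COMMENT     Fully synthetic map generated by scripts/make_plasmid_fixture.R;
COMMENT     layout mimics a PCR-only tagging plasmid for round-trip testing.
FEATURES             Location/Qualifiers
     source          1..526
                     /label="pPOT_synthetic"
     misc_feature    31..50
                     /label="fwd_anneal_N"
     CDS             91..156
                     /label="resistance_synthetic"
     CDS             197..310
                     /label="tag_orf_N"
     misc_feature    complement(290..310)
                     /label="rev_anneal_N"
     misc_feature    323..343
                     /label="fwd_anneal_C"
     CDS             323..436
                     /label="tag_orf_C"
     misc_feature    complement(477..496)
                     /label="rev_anneal_C"
ORIGIN
        1 gccttgacca ccgcactgcg tttcaaccga gaccagttga aagatgcgca agtgatgaca
       61 gtagaatcct aacgatagtt gtggattgtg atgtgtttga ctccaacgat ttgggatgac
      121 cagcctattg tgagcagtag atcgtctgag tcgtgatgta taccttaatt aaccagggga
      181 ccaggctaca ctacagatga tagcagcccg gttacagctt acgttattga gtactcttcg
      241 ccccgataca gcaggatttg aatggagacg ctgcgcatac tccgtgttag gaagtggttc
      301 tggtagtggt attcccgctt ggggttctgg tagtggttcc ggaggtgcgg tcgaccactg
      361 gaggatcggt tgccgtaaca ctgcagggca cctgcatgcc gtctcttcgc ggtgcgaagt
      421 ggaaagccag aaataatatt atttcagtag tactcactgg gccttagtga gcccctgcac
      481 aggtctctca aattggggac gcgactcggt gtaaccatcg cataca
//
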