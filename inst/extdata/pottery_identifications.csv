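sample,protein,accession,taxon,score,coverage_pct,n_peptides,n_unique,multispecies_taxa
100041M,Alpha-S1-casein,P02662,Bos taurus,97.97,10,3,3,
100051A,Beta-lactoglobulin,P02754,Bos taurus,83.68,8,2,2,Bubalus bubalis
100051A,Beta-casein,P02666,Bos taurus,76.82,12,2,2,Bubalus bubalis
100051D,Kappa-casein,P02668,Bos taurus,98.24,20,3,3,
100051D,Alpha-S1-casein,P02662,Bos taurus,97.35,21,6,6,
100051D,Alpha-S2-casein,P02663,Bos taurus,83.61,15,2,2,Ovis aries
100051D,Beta-casein,P02666,Bos taurus,79.64,12,3,3,Bubalus bubalis
100087C,Alpha-amylase/trypsin inhibitor CM3,P17314,Triticum aestivum,98.35,25,2,2,
100087C,Purothionin A-1,P01543,Triticum aestivum,98.29,26,4,1,
100087C,Non-specific lipid-transfer protein (Fragment),P24296,Triticum aestivum,98.25,45,3,3,
100087C,Alpha-1-purothionin (Fragment),P01544,Triticum aestivum,98.24,27,3,2,
100087C,Puroindoline-B,Q10464,Triticum aestivum,75.95,18,2,2,
100087D,Alpha-amylase/trypsin inhibitor CM3,P17314,Triticum aestivum,98.41,40,3,3,
100087D,Alpha-amylase/trypsin inhibitor CM16,P16159,Triticum aestivum,98.07,13,2,2,
100087D,Alpha-amylase inhibitor 0.19,P01085,Triticum aestivum,82.99,33,2,2,
100087D,Chymotrypsin inhibitor WCI,P83207,Triticum aestivum,58.51,25,2,2,
100088B,Alpha-amylase inhibitor 0.28,P01083,Triticum aestivum,99.18,69,10,10,
100088B,Glutenin high molecular weight subunit DY10,P10387,Triticum aestivum,99.16,23,7,7,
100088B,Glutenin high molecular weight subunit DX5,P10388,Triticum aestivum,99.13,12,7,7,
100088B,Serpin-Z2B,P93692,Triticum aestivum,99.13,39,8,7,
100088B,Alpha-amylase/trypsin inhibitor CM3,P17314,Triticum aestivum,99.09,49,8,7,
100088B,Beta-amylase,P93594,Triticum aestivum,99.05,23,7,7,Hordeum vulgare
100088B,Alpha-amylase inhibitor 0.19,P01085,Triticum aestivum,99.04,78,10,10,
100088B,Alpha-amylase/trypsin inhibitor CM16,P16159,Triticum aestivum,98.92,55,9,9,
100088B,Alpha-1-purothionin,P01544,Triticum aestivum,98.84,38,4,2,
100088B,Alpha/beta-gliadin clone PW1215,P04726,Triticum aestivum,98.78,30,5,2,
100088B,Alpha-amylase/trypsin inhibitor CM1,P16850,Triticum aestivum,98.75,39,5,2,
100088B,Puroindoline-A,P33432,Triticum aestivum,98.73,45,7,7,
100088B,Alpha-amylase/trypsin inhibitor CM2,P16851,Triticum aestivum,98.38,39,4,2,
100088B,Purothionin A-1,P01543,Triticum aestivum,98.38,24,6,3,
100088B,"Aspartate aminotransferase, cytoplasmic",M7YLN2,Triticum urartu,98.35,13,3,3,Oryza sativa
100088B,Gamma-gliadin B,P06659,Triticum aestivum,98.34,22,5,5,
100088B,Avenin-like b3,P0CZ06,Triticum aestivum,98.30,16,4,2,
100088B,Avenin-like b1,Q2A783,Triticum aestivum,98.30,16,4,2,
100088B,Type-5 thionin,Q05806,Triticum aestivum,98.11,37,3,3,
100088B,Chitin-binding type-1 domain-containing protein,A0A446YZN0,Triticum durum,97.96,25,3,2,Hordeum vulgare; Secale cereale
100088B,Protein disulfide-isomerase,P52589,Triticum aestivum,95.93,8,3,3,Hordeum vulgare
100088B,Puroindoline-B,Q10464,Triticum aestivum,94.84,32,6,6,
100088B,Chymotrypsin inhibitor WCI,P83207,Triticum aestivum,92.04,25,2,2,
100088B,Non-specific lipid-transfer protein,P24296,Triticum aestivum,88.01,41,2,2,
100088B,Non-specific lipid-transfer protein 2G,P82900,Triticum aestivum,84.47,51,5,2,
100088B,Trypsin/alpha-amylase inhibitor CMX1/CMX3,Q43723,Triticum aestivum,84.37,22,3,3,
100088B,Triosephosphate isomerase cytosolic,P34937,Hordeum vulgare,84.01,10,2,2,Secale cereale
100088B,Alpha/beta-gliadin A-V,P04725,Triticum aestivum,83.87,14,4,2,
100088B,Wheatwin-1,O64392,Triticum aestivum,61.68,11,2,2,
100088B,16.9 kDa class I heat shock protein 1,P12810,Triticum aestivum,61.68,13,2,2,
100088B,Protein H2A.7,Q43312,Triticum aestivum,61.66,25,2,2,Oryza sativa; Mytilus edulis; etc.
100088B,Carbonic anhydrase chloroplastic,P40880,Hordeum vulgare,60.88,9,2,2,
100088D,Alpha-amylase inhibitor 0.28,P01083,Triticum aestivum,98.21,27,3,3,
100088D,Alpha-amylase inhibitor 0.19,P01085,Triticum aestivum,79.95,37,3,3,
100088D,Purothionin A-1,P01543,Triticum aestivum,98.88,29,9,5,
100088D,Alpha-1-purothionin,P01544,Triticum aestivum,98.84,40,7,4,
100088D,Glutenin high molecular weight subunit DY10,P10387,Triticum aestivum,98.74,7,4,4,
100088D,Alpha-amylase/trypsin inhibitor CM16,P16159,Triticum aestivum,61.46,28,4,4,
100088D,Alpha-amylase/trypsin inhibitor CM2,P16851,Triticum aestivum,83.47,52,6,6,
100088D,Alpha-amylase/trypsin inhibitor CM3,P17314,Triticum aestivum,99.05,48,7,6,
100088D,Non-specific lipid-transfer protein,P24296,Triticum aestivum,97.25,80,8,8,
100088D,Alpha-2-purothionin,P32032,Triticum aestivum,98.86,40,9,5,
100088D,Puroindoline-A,P33432,Triticum aestivum,99.00,55,9,9,
100088D,Protein disulfide-isomerase,P52589,Triticum aestivum,97.82,8,4,4,
100088D,Non-specific lipid-transfer protein 2G,P82900,Triticum aestivum,98.39,65,7,5,
100088D,Beta-amylase,P93594,Triticum aestivum,98.10,8,4,4,Hordeum vulgare
100088D,Chymotrypsin inhibitor WCI,P83207,Triticum aestivum,91.58,39,4,4,
100088D,Puroindoline-B,Q10464,Triticum aestivum,61.23,9,2,2,
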