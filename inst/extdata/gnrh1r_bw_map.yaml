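# Ballesteros-Weinstein map for the human GnRH1 receptor (author numbering).
# Format: "<TM>.<position>": "<chain>/<residue number>/<3-letter name>"
# The chain id is configurable because deposited models differ in labelling.
"1.29": "A/32/THR"
"1.35": "A/38/ARG"
"1.39": "A/42/THR"
"1.52": "A/55/SER"
"1.53": "A/56/PHE"
"1.56": "A/59/LYS"
"1.58": "A/61/GLN"
"1.59": "A/62/LYS"
"1.60": "A/63/TRP"
"2.38": "A/75/ARG"
"2.44": "A/81/LYS"
"2.50": "A/87/ASN"
"2.53": "A/90/GLU"
"2.60": "A/98/ASP"
"2.64": "A/102/ASN"
"3.32": "A/121/LYS"
"3.36": "A/125/MET"
"3.40": "A/129/ALA"
"3.47": "A/136/SER"
"3.49": "A/138/ASP"
"3.50": "A/139/ARG"
"3.51": "A/140/SER"
"3.56": "A/145/ARG"
"4.61": "A/174/GLN"
"4.65": "A/178/PHE"
"5.32": "A/204/GLN"
"5.34": "A/206/TRP"
"5.35": "A/207/HIS"
"5.50": "A/223/PRO"
"5.58": "A/231/ASN"
"5.60": "A/233/LYS"
"5.67": "A/240/ARG"
"6.33": "A/265/THR"
"6.40": "A/272/PHE"
"6.44": "A/276/PHE"
"6.47": "A/279/CYS"
"6.48": "A/280/TRP"
"6.50": "A/282/PRO"
"6.51": "A/283/TYR"
"6.52": "A/284/TYR"
"6.54": "A/286/LEU"
"6.58": "A/290/TYR"
"7.30": "A/301/SER"
"7.31": "A/302/ASP"
"7.35": "A/306/HIS"
"7.37": "A/308/PHE"
"7.38": "A/309/PHE"
"7.49": "A/319/ASP"
"7.50": "A/320/PRO"
"7.51": "A/321/LEU"
"7.52": "A/322/ILE"
"7.53": "A/323/TYR"
"7.55": "A/325/TYR"
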