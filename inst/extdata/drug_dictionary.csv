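synonym,ingredient
DURVALUMAB,durvalumab
IMFINZI,durvalumab
MEDI4736,durvalumab
PEMBROLIZUMAB,pembrolizumab
KEYTRUDA,pembrolizumab
MK-3475,pembrolizumab
IPILIMUMAB,ipilimumab
YERVOY,ipilimumab
ATEZOLIZUMAB,atezolizumab
TECENTRIQ,atezolizumab
NIVOLUMAB,nivolumab
OPDIVO,nivolumab
CISPLATIN,cisplatin
PLATINOL,cisplatin
CIS-DIAMMINEDICHLOROPLATINUM,cisplatin
CDDP,cisplatin
CARBOPLATIN,carboplatin
PARAPLATIN,carboplatin
OXALIPLATIN,oxaliplatin
ELOXATIN,oxaliplatin
OXALIPLATINE,oxaliplatin
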