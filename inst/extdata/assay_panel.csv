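protein,peptide,charge,cv_raw,cv_tic,precursor_quant,role,bp_labeled
FLAGTTR,AADDTWEPFASGK,2,0.0976,0.0485,FALSE,analyte,TRUE
cytAPEX,LAFHSAGTFDK,3,0.1392,0.0773,TRUE,normalization_factor,TRUE
cytAPEX,EGLLQLPSDK,2,0.0787,0.0551,TRUE,normalization_factor,TRUE
cytAPEX,ALLSDPVFRPLVDK,2,0.0685,0.0914,TRUE,normalization_factor,TRUE
cytAPEX,LSELGFADALQLPPLER,2,0.1799,0.1126,TRUE,normalization_factor,TRUE
GAPDH,GALQNIIPASTGAAK,2,0.0793,0.0614,FALSE,normalization_factor,TRUE
ACTB,VAPEEHPVLLTEAPLNPK,3,0.0995,0.0511,TRUE,normalization_factor,TRUE
TUBA1,TIGGGDDSFNTFFSETGAGK,2,0.0424,0.0564,TRUE,normalization_factor,TRUE
TUBA1,AVFVDLEPTVIDEVR,2,0.1114,0.0747,TRUE,normalization_factor,TRUE
TUBA1,DVNAAIATIK,2,0.1031,0.0518,TRUE,normalization_factor,TRUE
HSPA1A,AQIHDLVLVGGSTR,2,0.1151,0.1357,FALSE,qc,TRUE
BiP,TWNDPSVQQDIK,2,0.1126,0.0461,FALSE,qc,FALSE
BiP,IEWLESHQDADIEDFK,3,0.0736,0.0591,FALSE,qc,FALSE
Avidin,SSVNDIGDDWK,2,0.1098,0.0395,TRUE,qc,FALSE
PC,ENNVDAVHPGYGFLSER,3,0.0802,0.0760,FALSE,normalization_factor,FALSE
PC,VVEIAPAAHLDPQLR,3,0.0560,0.0586,FALSE,normalization_factor,FALSE
PC,LDNASAFQGAVISPHYDSLLVK,3,0.0622,0.0681,FALSE,normalization_factor,FALSE
PC,VFDYSEYWEGAR,2,0.0801,0.0426,FALSE,normalization_factor,FALSE
PC,AEAEAQAEELSFPR,2,0.0845,0.0549,FALSE,normalization_factor,FALSE
PC,DFTATFGPLDSLNTR,2,0.1039,0.0373,FALSE,normalization_factor,FALSE
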