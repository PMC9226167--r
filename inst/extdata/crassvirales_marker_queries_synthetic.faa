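>crass_terminase synthetic_query_seed
RQTWEVKIREQYATEDNSTAVNKKIQVKIVRFGLNDSNKWPLKHYSVRKNIEDCKLNWYW
MVKIDPCAENYTQPNYQKKRHCLWYCLAVNWCNIWHPSITEEANYKASSKTDHSQNLWVT
FPEVPYGKSRWKPMMFYETKMHQVESGITQDIKVSEQMYARVCHTNKLGWDKWPQQGFYK
HCNGCMFPWVTCHVEIAHTVAPSQCTQQRNAVRDWNNLAMAVVDESMFIQPDRRHWNYEH
PADNIINDLGWQFTQLINGVPALLHLEFSWWHAGDYQGKRDSMGGTPLYYPKGERVAYGM
KYNNPSRLWNSNWLCWEASRMWVGFAMHSVTAVKDPVVQYVVHTLVVDVKFSQSKIFCDL
YEWAVNDIMIWGSRSVRDNFTNKLNAAFNVTGVCKSVVPSFHGKPCWNSRAEYVFIFNRA
WQCLSEPEFWRWNAEKKYTGQNLKVYENYCMYAMLFTFCLCVMQRELCIIPYPANKDTHP
EHEIHGRKVIHFVKCYCVASQDVWKMTMDQCFAACSLESSVTAQALIIRMWPVAGHYPPF
PMKHMLMACGLTACTPPPMN
>crass_polymerase synthetic_query_seed
SAQMLVPHGYKFMWGERVSVTGPDTQGFCTEQCDTTAAYGKMCHTMSMARKFSIMDSTPH
HKYSFYCRCHCMQKYNWQNFYDDEHDGCQNWNCMWDCNSPTTEMKEPFFMYVWDGLGCPK
YYMYTAHIYGPRWLLMKCSISTKFNLQWVYETIDQQGMLLSVMHTDEDFKIYTGTDMSLA
NFMSELNEMFTCTNCKWNYMPWYFMMNAPMVEYAKCMCSGNWDHNATPAHKKCDGSAHEQ
IKQQAYISERMLISWICCRIKAHKHSWTTEMDAITASLSAMRTNICGIIRSAHEEQAAWI
ETVPPQSPIHQVMTAYLPRYIIDRHVPILPQQESNSTRLQLNFMLKIRDWIKRLIMIFVP
RKYCLCWTEPWADCYLYVKPADYHIDDIENEWGQDMQTANTPHRIYPGRTPNMHGQCEKQ
SMPIKHIEDEYNRDDHDLHFWRSGTAEERPNAPCRQIIQFRPPALCNVFGWGEAQEAYTM
RVFCHEILWYSIIPWQLVMPCKWNEWHATEWEGNKSYLQEAKQEWEMKYRHCVIEAEWFN
LTFQIHQFHLITDYERLMSYPILWLSSHQEIWCLIWEGDHSINSFYGNMT
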