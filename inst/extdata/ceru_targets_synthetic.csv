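protein,glycosite,peptide,glycan,precursor_charge,expected_rt_min
CERU,138,EHEGAIYPDNTTDFQR,HexNAc(4)Hex(5)NeuAc(2),3,20.0
CERU,138,EHEGAIYPDNTTDFQR,HexNAc(4)Hex(5)Fuc(1)NeuAc(2),3,20.4
CERU,138,EHEGAIYPDNTTDFQR,HexNAc(5)Hex(6)NeuAc(3),3,19.2
CERU,138,EHEGAIYPDNTTDFQR,HexNAc(5)Hex(6)Fuc(2)NeuAc(3),3,19.6
CERU,358,ATFNETMDYR,HexNAc(4)Hex(5)NeuAc(2),2,25.0
CERU,358,ATFNETMDYR,HexNAc(5)Hex(6)NeuAc(3),3,24.3
CERU,397,ENLTAPGSDSAVFFEQGTTR,HexNAc(4)Hex(5)NeuAc(2),3,33.0
CERU,397,ENLTAPGSDSAVFFEQGTTR,HexNAc(4)Hex(5)Fuc(1)NeuAc(2),3,33.5
CERU,397,ENLTAPGSDSAVFFEQGTTR,HexNAc(5)Hex(6)NeuAc(3),3,32.1
CERU,397,ENLTAPGSDSAVFFEQGTTR,HexNAc(5)Hex(6)Fuc(2)NeuAc(3),3,32.6
CERU,762,ELHHLQEQNVSNAFLDK,HexNAc(4)Hex(5)NeuAc(1),3,39.0
CERU,762,ELHHLQEQNVSNAFLDK,HexNAc(4)Hex(5)Fuc(1)NeuAc(1),3,39.5
CERU,762,ELHHLQEQNVSNAFLDK,HexNAc(4)Hex(5)NeuAc(2),3,40.0
CERU,762,ELHHLQEQNVSNAFLDK,HexNAc(4)Hex(5)Fuc(1)NeuAc(2),3,40.5
CERU,762,ELHHLQEQNVSNAFLDK,HexNAc(5)Hex(6)NeuAc(2),3,38.2
CERU,762,ELHHLQEQNVSNAFLDK,HexNAc(5)Hex(6)Fuc(1)NeuAc(2),3,38.7
CERU,762,ELHHLQEQNVSNAFLDK,HexNAc(5)Hex(6)NeuAc(3),4,41.0
CERU,762,ELHHLQEQNVSNAFLDK,HexNAc(5)Hex(6)Fuc(2)NeuAc(3),4,41.5
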