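id,group,Cs1g16760,Cs1g23450,Cs2g19680,Cs2g31250,Cs4g07130,Cs4g15590,Cs5g15460,Cs7g10980,Cs7g31800,Cs9g04300,Cs9g14320,Cs9g16170
Dayongjuhuaxin,WENDAN,1/2,2/5,1/1,5/5,3/5,2/2,4/7,5/10,1/1,4/5,1/2,1/2
Fujianwendan,WENDAN,1/2,5/5,2/4,2/4,3/3,1/2,4/6,7/9,1/1,1/2,1/6,3/4
Guanximiyou,WENDAN,2/2,5/5,1/1,4/5,1/2,1/2,4/6,6/6,1/3,1/2,1/1,4/4
Liangpingyou_cq,WENDAN,1/2,2/2,1/2,5/5,3/3,1/2,4/4,6/6,1/3,1/1,1/1,4/4
Dongguaquan,SHATIANYOU,2/3,2/5,2/2,5/5,3/4,2/2,4/7,6/8,1/3,3/4,6/7,3/6
Hejiangyou,SHATIANYOU,2/3,5/5,2/2,5/5,3/4,1/2,4/4,6/8,1/1,4/7,6/7,3/6
Hongxinshatianyou,SHATIANYOU,2/2,2/5,2/4,5/5,3/4,1/1,7/7,8/10,1/1,4/7,5/5,3/4
Lingnanshatianyou,SHATIANYOU,2/3,5/5,2/2,5/5,3/4,1/2,4/4,6/8,1/1,4/7,6/7,3/6
Meiweishatianyou,SHATIANYOU,2/2,5/5,2/2,5/5,4/4,1/2,4/7,6/8,1/1,7/7,5/7,2/3
Zhaipoyou,SHATIANYOU,2/3,5/5,1/2,5/5,2/3,2/2,4/7,6/8,1/1,1/7,1/6,-
Zuoshiyou,PUMMELO,1/2,2/5,1/1,4/5,3/4,1/1,4/4,2/10,1/1,4/4,1/6,4/6
Unknown,PUMMELO,1/2,2/5,1/2,4/5,1/2,1/1,4/5,6/10,1/1,1/2,1/9,2/4
Dianjianghongxinyou,PUMMELO,1/2,2/2,1/2,5/5,1/4,1/1,7/7,4/10,-,4/4,1/6,6/6
Duanshiyou,PUMMELO,2/3,5/5,1/2,5/5,1/4,1/1,4/4,6/6,1/1,4/4,4/9,3/4
HB,PUMMELO,3/4,5/5,2/2,5/5,1/3,1/2,4/4,2/4,1/1,4/4,-,-
Humiyou,PUMMELO,2/2,2/4,2/2,3/5,3/3,1/2,4/7,3/10,1/1,1/4,1/3,4/4
Qiyou,PUMMELO,3/3,5/5,1/2,5/5,4/4,1/1,4/7,6/8,1/1,4/4,4/4,2/3
Shuhuayou,PUMMELO,2/2,2/5,1/2,5/5,3/4,1/2,4/7,6/10,1/1,7/7,5/7,3/4
Taiguomiyou,PUMMELO,2/3,2/3,1/1,4/5,3/4,2/2,4/4,2/10,1/1,4/4,1/7,2/3
Xianluodisuanyou,PUMMELO,1/2,5/5,1/1,5/5,3/4,1/1,4/4,10/10,1/3,4/7,1/1,4/4
Boluoxiangyou,HYBRID,1/1,1/2,2/3,1/5,1/4,1/3,1/4,1/10,1/3,1/1,1/3,4/5
Jiaodaoyou,HYBRID,1/2,5/5,2/3,6/7,1/6,2/4,4/5,10/10,1/1,6/8,1/6,-
Tangyouzi,HYBRID,2/4,1/5,2/3,5/9,1/6,1/3,2/4,1/5,2/4,6/6,3/8,-
Iwaikan,HYBRID,1/3,5/5,2/3,5/8,3/6,1/3,2/3,1/6,2/4,4/4,3/3,5/5
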