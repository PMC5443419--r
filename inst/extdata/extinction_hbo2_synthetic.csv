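# oxy-hemoglobin (HbO2) specific absorption spectrum
# synthetic: smooth parametric stand-in anchored to published literature values, not a digitized copy
# units: mM^-1 cm^-1 (base-10 specific absorption)
wavelength_nm,value
700,0.29
702,0.29364
704,0.29672
706,0.29948
708,0.30216
710,0.305
712,0.30824
714,0.31212
716,0.31688
718,0.32276
720,0.33
722,0.33867
724,0.34856
726,0.35949
728,0.37128
730,0.38375
732,0.39672
734,0.41001
736,0.42344
738,0.43683
740,0.45
742,0.46328
744,0.47704
746,0.49116
748,0.50552
750,0.52
752,0.53448
754,0.54884
756,0.56296
758,0.57672
760,0.59
762,0.6029
764,0.6156
766,0.6281
768,0.6404
770,0.6525
772,0.6644
774,0.6761
776,0.6876
778,0.6989
780,0.71
782,0.72081
784,0.73128
786,0.74147
788,0.75144
790,0.76125
792,0.77096
794,0.78063
796,0.79032
798,0.80009
800,0.81
802,0.819955
804,0.82984
806,0.839685
808,0.84952
810,0.859375
812,0.86928
814,0.879265
816,0.88936
818,0.899595
820,0.91
822,0.92073
824,0.93184
826,0.94321
828,0.95472
830,0.96625
832,0.97768
834,0.98889
836,0.99976
838,1.01017
840,1.02
842,1.02931
844,1.03824
846,1.04684
848,1.05512
850,1.06312
852,1.07088
854,1.07842
856,1.08576
858,1.09294
860,1.1
862,1.1069
864,1.1136
866,1.1201
868,1.1264
870,1.1325
872,1.1384
874,1.1441
876,1.1496
878,1.1549
880,1.16
882,1.16481
884,1.16928
886,1.17347
888,1.17744
890,1.18125
892,1.18496
894,1.18863
896,1.19232
898,1.19609
900,1.2
902,1.20424
904,1.20885
906,1.21368
908,1.21856
910,1.22333
912,1.22784
914,1.23192
916,1.23541
918,1.23816
920,1.24
922,1.2411
924,1.24174
926,1.24195
928,1.24176
930,1.24119
932,1.24026
934,1.239
936,1.23743
938,1.23558
940,1.23348
942,1.23115
944,1.22861
946,1.22589
948,1.22301
950,1.22
952,1.2168
954,1.21333
956,1.20963
958,1.20569
960,1.20155
962,1.19721
964,1.19269
966,1.18801
968,1.18319
970,1.17824
972,1.17318
974,1.16802
976,1.16279
978,1.1575
980,1.15216
982,1.14679
984,1.14142
986,1.13605
988,1.1307
990,1.12539
992,1.12013
994,1.11495
996,1.10986
998,1.10487
1000,1.1
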