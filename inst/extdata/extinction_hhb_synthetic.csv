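# deoxy-hemoglobin (HHb) specific absorption spectrum
# synthetic: smooth parametric stand-in anchored to published literature values, not a digitized copy
# units: mM^-1 cm^-1 (base-10 specific absorption)
wavelength_nm,value
700,1.79
702,1.7621
704,1.73212
706,1.7005
708,1.66769
710,1.63414
712,1.6003
714,1.56663
716,1.53357
718,1.50153
720,1.47084
722,1.44186
724,1.41494
726,1.39042
728,1.36866
730,1.35
732,1.33487
734,1.32406
736,1.31841
738,1.31879
740,1.32606
742,1.34107
744,1.36469
746,1.39766
748,1.43796
750,1.48081
752,1.52133
754,1.55463
756,1.57582
758,1.58
760,1.56384
762,1.53023
764,1.4836
766,1.42839
768,1.36904
770,1.31
772,1.25494
774,1.20452
776,1.15862
778,1.11715
780,1.08
782,1.04702
784,1.01789
786,0.992251
788,0.969742
790,0.95
792,0.932663
794,0.917364
796,0.903734
798,0.891402
800,0.88
802,0.869214
804,0.858948
806,0.849164
808,0.839819
810,0.830874
812,0.82229
814,0.814025
816,0.806041
818,0.798337
820,0.790948
822,0.783909
824,0.777258
826,0.771032
828,0.765267
830,0.76
832,0.755255
834,0.751004
836,0.747207
838,0.743826
840,0.740818
842,0.738146
844,0.735767
846,0.733644
848,0.731735
850,0.73
852,0.728406
854,0.726947
856,0.72562
858,0.724426
860,0.723363
862,0.722432
864,0.72163
866,0.720958
868,0.720415
870,0.72
872,0.719713
874,0.719554
876,0.719527
878,0.719631
880,0.71987
882,0.720245
884,0.720757
886,0.721408
888,0.722199
890,0.723134
892,0.724212
894,0.725436
896,0.726808
898,0.728328
900,0.73
902,0.731822
904,0.733789
906,0.735892
908,0.738123
910,0.740473
912,0.742935
914,0.7455
916,0.748161
918,0.750908
920,0.753734
922,0.756631
924,0.75959
926,0.762603
928,0.765662
930,0.768759
932,0.771885
934,0.775033
936,0.778194
938,0.78136
940,0.784522
942,0.787673
944,0.790805
946,0.793909
948,0.796976
950,0.8
952,0.802971
954,0.805883
956,0.808728
958,0.811499
960,0.81419
962,0.816792
964,0.819299
966,0.821703
968,0.823998
970,0.826177
972,0.828231
974,0.830155
976,0.831941
978,0.833581
980,0.835069
982,0.836398
984,0.83756
986,0.838548
988,0.839355
990,0.839974
992,0.840398
994,0.84062
996,0.840632
998,0.840428
1000,0.84
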